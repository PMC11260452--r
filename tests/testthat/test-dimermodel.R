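toy <- gen_toy_complex(bend_deg = 20)
toy_straight <- gen_toy_complex(bend_deg = 0)

test_that("trim is the identity at 0,0 and barely moves the bend for straight ends", {
  expect_identical(trim_duplex(toy, 0, 0), toy)
  trimmed <- trim_duplex(toy, 1, 1)
  b0 <- bend_angle(hdcoop:::complex_parts(toy)$duplex,
                   end_window = 2, trim_ends = 1)$bend_angle
  b1 <- bend_angle(hdcoop:::complex_parts(trimmed)$duplex,
                   end_window = 2, trim_ends = 1)$bend_angle
  expect_lt(abs(b1 - b0), 2)
  dup <- hdcoop:::complex_parts(trimmed)$duplex
  expect_equal(nrow(dup$pairing), 16)
})

test_that("trimming into the protein footprint errors with the nucleotide named", {
  expect_error(trim_duplex(toy, 5, 0), "protein-contacting nucleotide")
  expect_error(trim_duplex(toy, 0, 6), "protein-contacting nucleotide")
})

test_that("joining straight half-sites gives uniform ideal-B steps at the junction", {
  m <- join_as_dimer(toy_straight, 7, "preserve_bend")
  dup <- extract_duplex(m$structure, c("C", "D"))
  sp <- step_parameters(base_pair_frames(dup))
  expect_equal(sp$twist, rep(36, nrow(sp)), tolerance = 1e-3)
  expect_equal(sp$rise, rep(3.38, nrow(sp)), tolerance = 1e-3)
  expect_equal(sp$roll, rep(0, nrow(sp)), tolerance = 1e-3)
  expect_true(isTRUE(junction_continuity(m)))
})

test_that("the bend/spacer contrast reproduces: contact only for bent 7-bp spacing", {
  a_bent7 <- assess_dimer(join_as_dimer(toy, 7, "preserve_bend"))
  a_bent8 <- assess_dimer(join_as_dimer(toy, 8, "preserve_bend"))
  a_ideal7 <- assess_dimer(join_as_dimer(toy, 7, "ideal_b"))
  a_straight7 <- assess_dimer(join_as_dimer(toy_straight, 7, "preserve_bend"))

  cutoff <- 4.5
  expect_lt(a_bent7$min_interprotein_distance, cutoff)
  expect_equal(a_bent7$clash_count, 0)
  expect_gt(nrow(a_bent7$contacts), 0)
  expect_gt(length(a_bent7$interface_residues$protomer_a), 0)

  expect_gt(a_bent8$min_interprotein_distance, cutoff)
  expect_gt(a_ideal7$min_interprotein_distance, cutoff)
  expect_gt(a_straight7$min_interprotein_distance, cutoff)
  expect_equal(nrow(a_ideal7$contacts), 0)
  # spacer monotonicity on the bent fixture
  expect_gt(a_bent8$min_interprotein_distance,
            a_bent7$min_interprotein_distance)
})

test_that("join is rigid on each protomer and each retained DNA half", {
  m <- join_as_dimer(toy, 7, "preserve_bend")
  at <- m$structure$atoms
  orig_prot <- as.matrix(toy$atoms[toy$atoms$chain == "A", c("x", "y", "z")])
  for (ch in c("A", "B")) {
    got <- as.matrix(at[at$chain == ch, c("x", "y", "z")])
    expect_equal(dim(got), dim(orig_prot))
    expect_lt(max(abs(dist(got) - dist(orig_prot))), 1e-6)
  }
  # protomer A did not move at all
  expect_equal(as.matrix(at[at$chain == "A", c("x", "y", "z")]), orig_prot,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("each half of a preserve_bend model keeps the monomer bend", {
  m <- join_as_dimer(toy, 7, "preserve_bend")
  fr <- base_pair_frames(extract_duplex(m$structure, c("C", "D")))
  b_first <- bend_angle(fr[1:13], end_window = 2, trim_ends = 1)$bend_angle
  # the copy's kink sits at composite step 15-16; bracket it
  b_last <- bend_angle(fr[13:29], end_window = 2, trim_ends = 0)$bend_angle
  expect_lt(abs(b_first - 20), 2)
  expect_lt(abs(b_last - 20), 2)
})

test_that("joins are deterministic and refuse impossible geometry", {
  m1 <- join_as_dimer(toy, 7, "preserve_bend")
  m2 <- join_as_dimer(toy, 7, "preserve_bend")
  expect_identical(m1$structure$atoms, m2$structure$atoms)
  # the 18-bp toy duplex cannot host a 14-bp spacer (needs 20 bp)
  expect_error(join_as_dimer(toy, 14, "preserve_bend"), "too short")
})

test_that("assessment demands a continuous junction", {
  m <- join_as_dimer(toy, 7, "preserve_bend")
  at <- m$structure$atoms
  jl <- 13  # junction level: displace the downstream P to break the bond
  sel <- at$chain == "C" & at$resno == jl + 1 & at$name == "P"
  at$x[sel] <- at$x[sel] + 5
  broken <- m
  broken$structure <- new_structure(at, m$structure$metadata)
  expect_error(assess_dimer(broken), "discontinuous junction")
})

test_that("termini distances are reported for all four pairings", {
  a <- assess_dimer(join_as_dimer(toy, 7, "preserve_bend"))
  expect_named(a$termini_distances, c("n_n", "c_c", "n_c", "c_n"))
  expect_true(all(a$termini_distances > 0))
  expect_equal(a$n_term_distance, unname(a$termini_distances["n_n"]))
})
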