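test_that("ideal B-form builds are straight with canonical step geometry", {
  for (seq in c("TGAGCTAATTAAAGC", "ACGTACGTACGT", "AAAAAAAAAAA")) {
    d <- build_duplex(seq)
    expect_equal(bend_angle(d)$bend_angle, 0, tolerance = 1e-6)
    sp <- step_parameters(base_pair_frames(d))
    expect_equal(sp$twist, rep(36, nchar(seq) - 1), tolerance = 1e-6)
    expect_equal(sp$rise, rep(3.38, nchar(seq) - 1), tolerance = 1e-6)
  }
  # 11-mer: end-to-end axis length is 10 rises
  d11 <- build_duplex("ACGTACGTACG")
  fr <- base_pair_frames(d11)
  expect_equal(sqrt(sum((fr[[11]]$origin - fr[[1]]$origin)^2)), 10 * 3.38,
               tolerance = 1e-6)
})

test_that("builder rejects invalid sequences and step tables", {
  expect_error(build_duplex("ACGX"), "non-ACGT")
  expect_error(build_duplex("A"), "length >= 2")
  expect_error(build_duplex("ACGT", steps = data.frame(shift = 0)), "columns")
  st <- random_steps(2)
  expect_error(build_duplex("ACGT", steps = st), "3 steps")
})

test_that("builder and analyzer are mutual inverses over random steps", {
  st <- random_steps(100, seed = 42)
  d <- build_duplex(paste(withr::with_seed(7,
    sample(c("A", "C", "G", "T"), 101, TRUE)), collapse = ""), steps = st)
  sp <- step_parameters(base_pair_frames(d))
  expect_equal(as.matrix(sp), as.matrix(st), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("frames are rigid-motion equivariant and detect a single roll", {
  d <- kinked_duplex(n = 10, at = 5, roll = 5)
  fr <- base_pair_frames(d)
  z <- function(f) f$R[, 3]
  angles <- vapply(1:8, function(i) {
    acos(min(1, sum(z(fr[[i]]) * z(fr[[i + 1]])))) * 180 / pi
  }, numeric(1))
  expect_equal(angles[5], 5, tolerance = 1e-6)
  expect_lt(max(angles[-5]), 1e-4)

  R <- random_rotation(3)
  moved <- d
  moved$structure <- rigid_move(d$structure, R, c(10, -4, 2))
  fr2 <- base_pair_frames(moved)
  for (i in c(1, 5, 10)) {
    expect_equal(fr2[[i]]$R, R %*% fr[[i]]$R, tolerance = 1e-8)
  }
})

test_that("bend angle matches a direct rotation-composition oracle", {
  roll <- 13; tilt <- -6
  d <- kinked_duplex(n = 15, at = 7, roll = roll, tilt = tilt)
  # oracle: helical axes before/after the kink differ by the kink's
  # z-axis rotation, computed by composing the step rotation matrices
  gam <- sqrt(roll^2 + tilt^2) * pi / 180
  phi <- atan2(tilt, roll)
  om <- 36 * pi / 180
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  Rkink <- rz(om / 2 - phi) %*% ry(gam) %*% rz(om / 2 + phi)
  oracle <- acos(min(1, (Rkink %*% c(0, 0, 1))[3])) * 180 / pi
  b <- bend_angle(d, end_window = 3, trim_ends = 1)
  expect_equal(b$bend_angle, oracle, tolerance = 1e-6)
  # the per-step bend localizes the kink at step 7
  expect_true(which.max(b$per_step_bend) %in% c(6, 7))
  expect_lt(max(b$per_step_bend[-(6:7)]), 1e-6)
})

test_that("bend angle is invariant under global rigid motion", {
  d <- kinked_duplex(n = 14, at = 6, roll = 20)
  b0 <- bend_angle(d, end_window = 2, trim_ends = 1)$bend_angle
  for (s in 1:5) {
    moved <- d
    moved$structure <- rigid_move(d$structure, random_rotation(s),
                                  withr::with_seed(s, rnorm(3, 0, 20)))
    expect_equal(bend_angle(moved, end_window = 2, trim_ends = 1)$bend_angle,
                 b0, tolerance = 1e-6)
  }
  expect_equal(b0, 20, tolerance = 1e-6)
})

test_that("bend errors when the end windows would overlap", {
  d <- build_duplex("ACGTACGT")
  expect_error(bend_angle(d), "end windows overlap")
})

test_that("groove widths follow the P-P minus 5.8 convention, uniform on ideal builds", {
  d <- build_duplex(strrep("GC", 10))
  g <- groove_profile(d)
  inner <- g$minor_width[g$defined_minor]
  expect_true(max(inner) - min(inner) < 0.1)
  expect_true(all(g$minor_width >= 0, na.rm = TRUE))
  expect_true(all(is.na(g$minor_width[c(1, 20)])))  # ends undefined, not 0

  # direct substitution: width = cross-strand P-P distance - 5.8
  P <- hdcoop:::phosphate_levels(d)
  i <- 10
  pp <- sqrt(sum((P$sense[i + 1, ] - P$anti[i - 1, ])^2))
  expect_equal(g$minor_width[i], pp - 5.8, tolerance = 1e-9)

  # strand relabeling of a palindromic ideal duplex leaves widths unchanged
  e <- extract_duplex(d$structure, c("B", "A"))
  g2 <- groove_profile(e)
  expect_equal(mean(g2$minor_width, na.rm = TRUE),
               mean(g$minor_width, na.rm = TRUE), tolerance = 1e-6)
})

test_that("A/T-rich sequence-dependent builds have narrower minor grooves", {
  gat <- groove_profile(build_duplex(strrep("AT", 10), "sequence_dependent"))
  ggc <- groove_profile(build_duplex(strrep("GC", 10), "sequence_dependent"))
  expect_lt(mean(gat$minor_width, na.rm = TRUE),
            mean(ggc$minor_width, na.rm = TRUE))
})

test_that("shape profiles are deterministic, end-flagged and strand-symmetric", {
  seq <- "TGAGCTAATTAAAGC"
  s1 <- predict_shape(seq)
  s2 <- predict_shape(seq)
  expect_identical(s1, s2)
  expect_false(any(s1$defined[c(1, nchar(seq))]))
  # minor groove width is strand-symmetric: reverse complement reverses it
  sr <- predict_shape(hdcoop:::revcomp(seq))
  expect_equal(s1$minor_groove_width, rev(sr$minor_groove_width),
               tolerance = 1e-9)
  expect_error(predict_shape("ACG"), "length >= 2|shorter")
})

test_that("A/T-spacer probes have larger propeller magnitude than G/C over the spacer", {
  at_probe <- paste0("GCGC", "TAAT", "GGTATAT", "TAAT", "GCGC")
  gc_probe <- paste0("GCGC", "TAAT", "GGCGCGC", "TAAT", "GCGC")
  sp_at <- predict_shape(at_probe)
  sp_gc <- predict_shape(gc_probe)
  spacer_pos <- 11:15  # analyzed spacer positions within the probe
  expect_gt(mean(abs(sp_at$propeller_twist[spacer_pos])),
            mean(abs(sp_gc$propeller_twist[spacer_pos])))
})
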