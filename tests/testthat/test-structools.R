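test_that("superposition is exact on identity and transformed copies", {
  cx <- gen_toy_complex(bend_deg = 15)
  self <- superpose(cx, cx)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)

  R <- random_rotation(11); tr <- c(7, -2, 4)
  moved <- rigid_move(cx, R, tr)
  fit <- superpose(moved, cx)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  # the recovered transform inverts the applied one
  expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
})

test_that("superposition rmsd agrees with brute force after the transform", {
  cx <- gen_toy_complex(bend_deg = 10)
  moved <- rigid_move(cx, random_rotation(4), c(3, 3, 3))
  # perturb to make the fit non-trivial
  moved$atoms$x <- moved$atoms$x + withr::with_seed(5,
    rnorm(nrow(moved$atoms), 0, 0.3))
  fit <- superpose(moved, cx)
  applied <- transform_structure(moved, fit$rotation, fit$translation)
  brute <- sqrt(mean(rowSums((as.matrix(applied$atoms[, c("x", "y", "z")]) -
                              as.matrix(cx$atoms[, c("x", "y", "z")]))^2)))
  expect_equal(fit$rmsd, brute, tolerance = 1e-9)
  # cross-check against the independent bio3d fit
  bref <- bio3d::rmsd(as.numeric(t(as.matrix(cx$atoms[, c("x", "y", "z")]))),
                      as.numeric(t(as.matrix(moved$atoms[, c("x", "y", "z")]))),
                      fit = TRUE)
  expect_lt(abs(fit$rmsd - bref), 1.1e-3)  # bio3d rounds to 3 decimals
})

test_that("superposition errors on too-few or collinear matches", {
  mk <- function(xyz) new_structure(data.frame(
    serial = seq_len(nrow(xyz)), name = "CA", resname = "GLY", chain = "A",
    resno = seq_len(nrow(xyz)), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = "C", occ = 1, b = 0))
  two <- mk(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(superpose(two, two), "fewer than 3")
  line <- mk(cbind(0:4, 0, 0))
  expect_error(superpose(line, line), "collinear")
})

test_that("strict matching reports identity mismatches", {
  cx <- gen_toy_complex()
  other <- cx
  other$atoms$name[1] <- "CB"
  expect_error(superpose(other, cx, strict = TRUE), "strict matching failed")
})

test_that("SASA matches closed forms for isolated and paired spheres", {
  mk <- function(xyz, el = "S") new_structure(data.frame(
    serial = seq_len(nrow(xyz)), name = "S", resname = "X", chain = "A",
    resno = seq_len(nrow(xyz)), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = el, occ = 1, b = 0))
  one <- mk(rbind(c(0, 0, 0)))
  r1 <- 1.8 + 1.4
  expect_equal(sasa(one)$total, 4 * pi * r1^2, tolerance = 1e-9)

  far <- mk(rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(sasa(far)$total, 2 * 4 * pi * r1^2, tolerance = 1e-9)

  # two overlapping equal spheres: analytic spherical-cap oracle
  d <- 2.5
  pair <- mk(rbind(c(0, 0, 0), c(d, 0, 0)))
  h <- r1 - d / 2  # cap height removed from each sphere
  oracle <- 2 * (4 * pi * r1^2 - 2 * pi * r1 * h)
  got <- sasa(pair)$total
  expect_lt(abs(got - oracle) / oracle, 0.01)
})

test_that("SASA is invariant under rigid motion and atom reorder", {
  cx <- gen_toy_complex()
  prot <- subset_structure(cx, cx$atoms$chain == "A")
  s0 <- sasa(prot)
  expect_equal(s0$total, sum(s0$per_atom_area), tolerance = 1e-6)
  # rigid motion: invariant up to the quadrature anisotropy of the fixed
  # sphere-point set
  moved <- rigid_move(prot, random_rotation(2), c(30, -10, 5))
  expect_equal(sasa(moved)$total, s0$total, tolerance = 3e-3)
  expect_equal(sasa(moved, n_sphere_points = 5000)$total,
               sasa(prot, n_sphere_points = 5000)$total, tolerance = 1e-3)
  perm <- withr::with_seed(3, sample(nrow(prot$atoms)))
  reord <- prot
  reord$atoms <- prot$atoms[perm, ]
  reord$atoms$serial <- seq_len(nrow(reord$atoms))
  reord$atoms$resno <- seq_len(nrow(reord$atoms))
  expect_equal(sasa(reord)$total, s0$total, tolerance = 1e-6)
})

test_that("unknown elements error without a default radius", {
  odd <- new_structure(data.frame(serial = 1, name = "XX", resname = "LIG",
                                  chain = "A", resno = 1, x = 0, y = 0, z = 0,
                                  element = "W", occ = 1, b = 0))
  expect_error(sasa(odd), "no van der Waals radius")
  expect_equal(sasa(odd, default_radius = 1.7)$total,
               4 * pi * (1.7 + 1.4)^2, tolerance = 1e-9)
})

test_that("interface reports are symmetric and vanish for distant parts", {
  cx <- gen_toy_complex()
  prot <- subset_structure(cx, cx$atoms$chain == "A")
  dna <- subset_structure(cx, cx$atoms$chain %in% c("C", "D"))

  far <- rigid_move(prot, diag(3), c(100, 0, 0))
  rep_far <- interface_report(far, dna)
  expect_equal(rep_far$buried_area_half, 0, tolerance = 1e-6)
  expect_equal(nrow(rep_far$contact_pairs), 0)

  ab <- interface_report(prot, dna)
  ba <- interface_report(dna, prot)
  expect_gt(ab$buried_area_half, 100)
  expect_equal(ab$buried_area_half, ba$buried_area_half, tolerance = 1e-9)
  expect_equal(unname(ab$buried_area_per_component),
               unname(rev(ba$buried_area_per_component)), tolerance = 1e-9)
  # contact lists mirror up to pair orientation
  key_ab <- paste(ab$contact_pairs$resno_a, ab$contact_pairs$resno_b)
  key_ba <- paste(ba$contact_pairs$resno_b, ba$contact_pairs$resno_a)
  expect_setequal(key_ab, key_ba)
  expect_true(all(ab$contact_pairs$min_distance <= ab$cutoff))
})

test_that("increasing the contact cutoff never removes pairs", {
  cx <- gen_toy_complex()
  prot <- subset_structure(cx, cx$atoms$chain == "A")
  dna <- subset_structure(cx, cx$atoms$chain %in% c("C", "D"))
  p1 <- contact_pairs(prot, dna, 4.5)
  p2 <- contact_pairs(prot, dna, 6.0)
  k1 <- paste(p1$chain_b, p1$resno_a, p1$resno_b)
  k2 <- paste(p2$chain_b, p2$resno_a, p2$resno_b)
  expect_true(all(k1 %in% k2))
})

test_that("combining overlapping components is refused", {
  cx <- gen_toy_complex()
  prot <- subset_structure(cx, cx$atoms$chain == "A")
  expect_error(interface_report(prot, prot), "share atoms")
})
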