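test_that("spacer variants set 0.5/0.5 on the analyzed positions only", {
  pwm <- dimer_pwm()
  at <- make_spacer_variant(pwm, variant = "AT")
  pos <- 7:11  # motif coordinates of analyzed spacer positions 3-7
  expect_true(all(abs(at$mat[pos, c("A", "T")] - 0.499) < 1e-2))
  expect_true(all(at$mat[pos, c("C", "G")] < 0.01))
  expect_equal(rowSums(at$mat), rep(1, 15), tolerance = 1e-9)
  # locality: non-spacer columns bit-identical
  untouched <- setdiff(1:15, pos)
  expect_identical(at$mat[untouched, ], pwm$mat[untouched, ])
  # overwrite idempotence: AT then GC equals GC directly
  gc_direct <- make_spacer_variant(pwm, variant = "GC")
  gc_after <- make_spacer_variant(at, variant = "GC")
  expect_equal(gc_after$mat, gc_direct$mat, tolerance = 1e-12)
  # too-short matrix
  short <- motif_matrix(matrix(0.25, 10, 4))
  expect_error(make_spacer_variant(short), "cannot accommodate")
})

test_that("scanning finds the consensus at maximum score on both strands", {
  pwm <- make_spacer_variant(dimer_pwm(), variant = "AT")
  cons <- paste(colnames(pwm$mat)[apply(pwm$mat, 1, which.max)], collapse = "")
  hits <- scan_pwm(pwm, cons)
  expect_equal(hits$start[hits$strand == "+"], 1)
  expect_equal(max(hits$score_bits), max_score(pwm), tolerance = 1e-9)
  # reverse complement scores identically on the opposite strand
  hits_rc <- scan_pwm(pwm, hdcoop:::revcomp(cons))
  expect_equal(max(hits_rc$score_bits), max(hits$score_bits), tolerance = 1e-9)
  expect_true("-" %in% hits_rc$strand)
})

test_that("scan hits equal exhaustive enumeration on short sequences", {
  pwm <- make_spacer_variant(dimer_pwm(), variant = "AT")
  lw <- hdcoop:::log_odds_matrix(pwm)
  L <- nrow(lw)
  thr <- 0.8 * max_score(pwm)
  seqs <- withr::with_seed(9, c(
    vapply(1:8, function(i)
      paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = ""),
      character(1)),
    paste0("GC", "TAATGGTATATTAAT", "CG"),
    paste0(hdcoop:::revcomp("TAATGGAATATTAAT"), "ACGT")))
  for (s in seqs) {
    got <- scan_pwm(pwm, s)
    brute <- NULL
    for (st in seq_len(nchar(s) - L + 1)) {
      for (strand in c("+", "-")) {
        win <- substr(s, st, st + L - 1)
        if (strand == "-") win <- hdcoop:::revcomp(win)
        sc <- sum(vapply(seq_len(L), function(j)
          lw[j, substr(win, j, j)], numeric(1)))
        if (sc >= thr) {
          brute <- rbind(brute, data.frame(start = st, strand = strand,
                                           score_bits = sc))
        }
      }
    }
    n_brute <- if (is.null(brute)) 0 else nrow(brute)
    expect_equal(nrow(got), n_brute)
    if (n_brute > 0) {
      o1 <- got[order(got$start, got$strand), ]
      o2 <- brute[order(brute$start, brute$strand), ]
      expect_equal(o1$start, o2$start)
      expect_equal(o1$strand, o2$strand)
      expect_equal(o1$score_bits, o2$score_bits, tolerance = 1e-9)
    }
  }
})

test_that("scan is strand-symmetric with mirrored coordinates", {
  pwm <- dimer_pwm()
  s <- paste0("AG", "TAATCCTATATTAAT", "GGA")
  f <- scan_pwm(pwm, s)
  r <- scan_pwm(pwm, hdcoop:::revcomp(s))
  expect_equal(nrow(f), nrow(r))
  n_off <- nchar(s) - 15 + 1
  mirrored <- sort(n_off - r$start + 1)
  expect_equal(sort(f$start), mirrored)
  expect_setequal(r$strand, chartr("+-", "-+", f$strand))
})

test_that("N bases score as background, not errors", {
  pwm <- dimer_pwm()
  s <- paste0("TAATGGTATAT", "NNNN", "TAAT")
  expect_silent(h <- scan_pwm(pwm, s, threshold = list(bits = -100)))
  expect_gt(nrow(h), 0)
})

test_that("cycle enrichment counts each sequence once and honors order invariance", {
  at <- make_spacer_variant(dimer_pwm(), variant = "AT")
  cons <- paste(colnames(at$mat)[apply(at$mat, 1, which.max)], collapse = "")
  lib <- paste0("GCGCA", c(cons, cons, cons, cons), "TGCAG")
  ce <- cycle_enrichment(list(cycle0 = lib))
  expect_equal(ce$pct_AT, 100)
  shuffled <- cycle_enrichment(list(cycle0 = rev(lib)))
  expect_equal(ce$pct_AT, shuffled$pct_AT)
  expect_equal(ce$pct_GC, shuffled$pct_GC)
  # empty cycle: n = 0, percentage undefined
  ce0 <- cycle_enrichment(list(cycle0 = character(0)))
  expect_equal(ce0$n_sequences, 0)
  expect_true(is.na(ce0$pct_AT))
})

test_that("spacer G/C fractions follow the exclusion rule and orientation", {
  r <- spacer_gc_report("TAATGGCCCATTAAT")
  expect_equal(r$gc_fraction, 0.6)  # GG excluded, CCCAT analyzed
  # orientation by best strand: the reverse complement gives the same site
  r2 <- spacer_gc_report(hdcoop:::revcomp("TAATGGCCCATTAAT"))
  expect_equal(r2$gc_fraction, 0.6)
  expect_equal(r2$n_excluded, 0)
  # all-A spacers: fraction 0, A/T-skewed
  r3 <- spacer_gc_report(rep("TAATCCAAAAATAAT", 10))
  expect_equal(r3$mean_gc, 0)
  expect_equal(r3$skew_direction, "A/T-skewed")
  # unmatched sites are excluded with a count
  r4 <- spacer_gc_report(c("TAATGGCCCATTAAT", "GGGGGGGGGGGGGGG"))
  expect_equal(r4$n_sites, 1)
  expect_equal(r4$n_excluded, 1)
})

test_that("a composition-matched null sample passes the KS check", {
  edges <- c(-Inf, (0:4 + 0.5) / 5, Inf)
  mass <- diff(pnorm(edges, 0.5, 0.33))
  sites <- withr::with_seed(7, {
    counts <- rmultinom(1, 1000, mass)[, 1]
    unlist(lapply(0:5, function(j) {
      if (counts[j + 1] == 0) return(character(0))
      vapply(seq_len(counts[j + 1]), function(i)
        paste0("TAAT", "GG",
               paste(sample(c(rep("G", j), rep("A", 5 - j))), collapse = ""),
               "TAAT"), character(1))
    }))
  })
  r <- spacer_gc_report(sites)
  expect_lt(r$ks_statistic, 1.36 / sqrt(r$n_sites))
  expect_gt(r$ks_p, 0.05)
})
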