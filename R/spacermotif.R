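#' @title PWM spacer variants, scanning and spacer-composition analysis
#'
#' @description Construction of A/T- and G/C-rich spacer-variant position
#' weight matrices for a head-to-tail TAAT-N7-TAAT dimer site, log-odds
#' scanning of sequence libraries on both strands, per-cycle enrichment of
#' each variant across selection rounds, and the G/C-composition
#' distribution of spacers in oriented dimer sites versus a reference
#' normal distribution.
#' @name spacermotif
NULL

#' Head-to-tail dimer site definition
#'
#' Two TAAT half-sites on the same strand separated by a fixed spacer. The
#' protein footprint covers the first two spacer nucleotides, so
#' composition analysis is restricted to the remaining spacer positions
#' (indices 3..7 of a 7-bp spacer, 1-based within the spacer).
#'
#' @param half_site half-site consensus.
#' @param spacer_length spacer length, bp.
#' @param analyzed_spacer_positions spacer indices used for composition.
#' @return a `DimerSiteDefinition`.
#' @export
dimer_site <- function(half_site = "TAAT", spacer_length = 7,
                       analyzed_spacer_positions = 3:7) {
  if (any(analyzed_spacer_positions <= 2)) {
    stop("the first two spacer nucleotides are protein-contacted and ",
         "must be excluded from composition analysis")
  }
  if (any(analyzed_spacer_positions > spacer_length)) {
    stop("analyzed positions exceed the spacer length")
  }
  structure(list(half_site = half_site, spacer_length = spacer_length,
                 analyzed_spacer_positions = analyzed_spacer_positions,
                 orientation = "head-to-tail"),
            class = "DimerSiteDefinition")
}

# 1-based motif coordinates of the spacer within the dimer PWM.
spacer_motif_positions <- function(sites) {
  nh <- nchar(sites$half_site)
  seq(nh + 1, nh + sites$spacer_length)
}

#' Default head-to-tail dimer PWM
#'
#' A consensus-built TAAT-N7-TAAT matrix: strong half-site columns
#' (probability `core_p` on the consensus base) and near-uniform spacer
#' columns. Stands in for a selection-derived dimer matrix where none is
#' supplied.
#'
#' @param sites a `DimerSiteDefinition`.
#' @param core_p consensus-base probability in half-site columns.
#' @return a `MotifMatrix`.
#' @export
dimer_pwm <- function(sites = dimer_site(), core_p = 0.91) {
  bases <- c("A", "C", "G", "T")
  col_for <- function(b) {
    p <- rep((1 - core_p) / 3, 4)
    p[bases == b] <- core_p
    p
  }
  half <- t(vapply(strsplit(sites$half_site, "")[[1]], col_for, numeric(4)))
  spacer <- matrix(0.25, sites$spacer_length, 4)
  motif_matrix(rbind(half, spacer, half),
               name = sprintf("%s-N%d-%s", sites$half_site,
                              sites$spacer_length, sites$half_site))
}

#' Build an A/T- or G/C-rich spacer variant of a dimer PWM
#'
#' At the analyzed spacer positions the two variant bases get probability
#' 0.5 each and the other two bases the pseudocount floor (then
#' renormalized); all other columns are untouched. Applying one variant
#' after another overwrites (idempotent).
#'
#' @param pwm the dimer `MotifMatrix`.
#' @param sites a `DimerSiteDefinition`.
#' @param variant `"AT"` or `"GC"`.
#' @return modified `MotifMatrix`.
#' @export
make_spacer_variant <- function(pwm, sites = dimer_site(),
                                variant = c("AT", "GC")) {
  variant <- match.arg(variant)
  L <- motif_length(pwm)
  need <- 2 * nchar(sites$half_site) + sites$spacer_length
  if (L < need) {
    stop("PWM length ", L, " cannot accommodate two half-sites plus spacer (",
         need, ")")
  }
  pos <- spacer_motif_positions(sites)[sites$analyzed_spacer_positions]
  keep <- if (variant == "AT") c("A", "T") else c("G", "C")
  floor_p <- pwm$pseudocount
  row <- stats::setNames(rep(floor_p, 4), c("A", "C", "G", "T"))
  row[keep] <- 0.5
  row <- row / sum(row)
  out <- pwm
  out$mat[pos, ] <- matrix(row[colnames(out$mat)], length(pos), 4, byrow = TRUE)
  out$name <- paste0(pwm$name, "_", variant)
  out
}

# Integer encoding A=1 C=2 G=3 T=4; other letters 0 (scored as background).
encode_dna <- function(sequence) {
  v <- match(strsplit(toupper(sequence), "")[[1]], c("A", "C", "G", "T"))
  v[is.na(v)] <- 0L
  v
}

log_odds_matrix <- function(pwm) {
  p <- pmax(pwm$mat, pwm$pseudocount)
  p <- p / rowSums(p)
  log2(sweep(p, 2, pwm$background, `/`))
}

#' Maximum attainable log-odds score of a PWM
#' @param pwm a `MotifMatrix`.
#' @return score in bits.
#' @export
max_score <- function(pwm) sum(apply(log_odds_matrix(pwm), 1, max))

# All-offset log-odds scores of an encoded sequence on one strand.
scores_one_strand <- function(enc, lw) {
  L <- nrow(lw)
  n <- length(enc)
  n_off <- n - L + 1
  if (n_off < 1) return(numeric(0))
  out <- numeric(n_off)
  for (j in seq_len(L)) {
    b <- enc[j:(j + n_off - 1)]
    contrib <- numeric(n_off)
    known <- b > 0
    contrib[known] <- lw[j, ][b[known]]
    out <- out + contrib  # unknown base scores 0 (background)
  }
  out
}

#' Scan a sequence with a PWM on both strands
#'
#' Log-odds scores (base 2, versus the PWM background) at every offset on
#' both strands; hits are positions scoring at or above the threshold.
#' `N` bases score as background (0 bits), not errors.
#'
#' @param pwm a `MotifMatrix`.
#' @param sequence DNA text (or a row of [read_reads()] output).
#' @param threshold either `list(fraction_of_max = f)` or
#'   `list(bits = x)`.
#' @param id sequence identifier carried into the hits.
#' @return data.frame of hits: `id`, `start` (1-based), `strand`,
#'   `score_bits`.
#' @export
scan_pwm <- function(pwm, sequence, threshold = list(fraction_of_max = 0.8),
                     id = "seq") {
  L <- motif_length(pwm)
  if (nchar(sequence) < L) stop("sequence shorter than the PWM")
  thr <- if (!is.null(threshold$bits)) threshold$bits
  else threshold$fraction_of_max * max_score(pwm)
  lw <- log_odds_matrix(pwm)
  fwd <- scores_one_strand(encode_dna(sequence), lw)
  rev_scores <- scores_one_strand(encode_dna(revcomp(sequence)), lw)
  n_off <- length(fwd)
  hits_f <- which(fwd >= thr)
  hits_r <- which(rev_scores >= thr)
  out <- rbind(
    if (length(hits_f) > 0)
      data.frame(id = id, start = hits_f, strand = "+",
                 score_bits = fwd[hits_f]),
    if (length(hits_r) > 0)
      # map reverse-strand offset back to forward coordinates
      data.frame(id = id, start = n_off - hits_r + 1, strand = "-",
                 score_bits = rev_scores[hits_r])
  )
  if (is.null(out)) {
    out <- data.frame(id = character(0), start = integer(0),
                      strand = character(0), score_bits = numeric(0))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# Fast per-read predicate/summary used by enrichment and the SELEX
# simulator: best score over both strands (and the matching hit).
best_hit <- function(enc, enc_rc, lw) {
  f <- scores_one_strand(enc, lw)
  r <- scores_one_strand(enc_rc, lw)
  bf <- if (length(f) > 0) max(f) else -Inf
  br <- if (length(r) > 0) max(r) else -Inf
  if (bf >= br) {
    list(score = bf, strand = "+", start = which.max(f))
  } else {
    list(score = br, strand = "-", start = which.max(r))
  }
}

#' Per-cycle motif enrichment across selection rounds
#'
#' For each cycle, the percentage of sequences with at least one hit to
#' the A/T-spacer variant PWM and to the G/C-spacer variant PWM (a
#' sequence counts once regardless of hit multiplicity).
#'
#' @param libraries named list: cycle label -> data.frame from
#'   [read_reads()] (or character vector of sequences).
#' @param pwm base dimer `MotifMatrix`.
#' @param sites a `DimerSiteDefinition`.
#' @param threshold hit threshold, as in [scan_pwm()].
#' @return a `CycleEnrichment` data.frame: per cycle `n_sequences`,
#'   `n_AT`, `n_GC`, `pct_AT`, `pct_GC` (percentages NA when n = 0).
#' @export
cycle_enrichment <- function(libraries, pwm = dimer_pwm(),
                             sites = dimer_site(),
                             threshold = list(fraction_of_max = 0.8)) {
  if (length(libraries) < 1) stop("need at least one cycle")
  at_pwm <- make_spacer_variant(pwm, sites, "AT")
  gc_pwm <- make_spacer_variant(pwm, sites, "GC")
  lw_at <- log_odds_matrix(at_pwm)
  lw_gc <- log_odds_matrix(gc_pwm)
  thr_at <- if (!is.null(threshold$bits)) threshold$bits
  else threshold$fraction_of_max * max_score(at_pwm)
  thr_gc <- if (!is.null(threshold$bits)) threshold$bits
  else threshold$fraction_of_max * max_score(gc_pwm)
  rows <- lapply(names(libraries), function(cyc) {
    lib <- libraries[[cyc]]
    seqs <- if (is.data.frame(lib)) lib$sequence else lib
    n <- length(seqs)
    if (n == 0) {
      return(data.frame(cycle = cyc, n_sequences = 0L, n_AT = 0L, n_GC = 0L,
                        pct_AT = NA_real_, pct_GC = NA_real_))
    }
    n_at <- 0L; n_gc <- 0L
    for (s in seqs) {
      enc <- encode_dna(s); enc_rc <- encode_dna(revcomp(s))
      if (best_hit(enc, enc_rc, lw_at)$score >= thr_at) n_at <- n_at + 1L
      if (best_hit(enc, enc_rc, lw_gc)$score >= thr_gc) n_gc <- n_gc + 1L
    }
    data.frame(cycle = cyc, n_sequences = n, n_AT = n_at, n_GC = n_gc,
               pct_AT = 100 * n_at / n, pct_GC = 100 * n_gc / n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("CycleEnrichment", "data.frame")
  out
}

#' Spacer G/C-composition report for oriented dimer sites
#'
#' Each input site is oriented by the best log-odds strand of the full
#' dimer PWM and must then match half-site + spacer + half-site; the G/C
#' fraction is computed over the analyzed spacer positions (the first two
#' spacer bases are protein-contacted and excluded). The empirical
#' distribution is compared to Normal(0.5, 0.33) by a Kolmogorov-Smirnov
#' statistic, with the direction of the mean shift.
#'
#' @param site_sequences character vector of dimer-site sequences (each
#'   exactly the site length).
#' @param sites a `DimerSiteDefinition`.
#' @param pwm dimer `MotifMatrix` used for orientation.
#' @param ref_mean,ref_sd reference normal parameters.
#' @return a `SpacerGCReport`: per-site fractions, KS statistic/p, mean
#'   shift sign, and the count of unmatched (excluded) sites.
#' @export
spacer_gc_report <- function(site_sequences, sites = dimer_site(),
                             pwm = dimer_pwm(sites),
                             ref_mean = 0.5, ref_sd = 0.33) {
  L <- motif_length(pwm)
  half <- sites$half_site
  nh <- nchar(half)
  pos <- spacer_motif_positions(sites)[sites$analyzed_spacer_positions]
  lw <- log_odds_matrix(pwm)
  fractions <- numeric(0)
  excluded <- 0L
  for (s in site_sequences) {
    if (nchar(s) != L) { excluded <- excluded + 1L; next }
    enc <- encode_dna(s); enc_rc <- encode_dna(revcomp(s))
    sc_f <- scores_one_strand(enc, lw)
    sc_r <- scores_one_strand(enc_rc, lw)
    oriented <- if (sc_f >= sc_r) toupper(s) else revcomp(s)
    halves_ok <- substr(oriented, 1, nh) == half &&
      substr(oriented, nh + sites$spacer_length + 1, L) == half
    if (!halves_ok) { excluded <- excluded + 1L; next }
    bases <- strsplit(oriented, "")[[1]][pos]
    fractions <- c(fractions, mean(bases %in% c("G", "C")))
  }
  # The attainable G/C fractions are discrete (j/n_pos): the reference
  # normal is integrated over the matching bins, otherwise the KS
  # statistic would be dominated by discreteness rather than composition.
  ks_stat <- NA_real_; ks_p <- NA_real_
  if (length(fractions) >= 3) {
    n_pos <- length(pos)
    vals <- (0:n_pos) / n_pos
    edges <- c(-Inf, (0:(n_pos - 1) + 0.5) / n_pos, Inf)
    ref_cdf <- cumsum(diff(stats::pnorm(edges, ref_mean, ref_sd)))
    emp_cdf <- vapply(vals, function(v) mean(fractions <= v + 1e-9),
                      numeric(1))
    ks_stat <- max(abs(emp_cdf - ref_cdf))
    # conservative asymptotic p from the Kolmogorov distribution
    lam <- (sqrt(length(fractions)) + 0.12 +
              0.11 / sqrt(length(fractions))) * ks_stat
    kk <- 1:100
    ks_p <- min(1, max(0, 2 * sum((-1)^(kk - 1) * exp(-2 * lam^2 * kk^2))))
  }
  structure(list(
    gc_fraction = fractions,
    n_sites = length(fractions), n_excluded = excluded,
    mean_gc = if (length(fractions) > 0) mean(fractions) else NA_real_,
    reference = c(mean = ref_mean, sd = ref_sd),
    ks_statistic = ks_stat,
    ks_p = ks_p,
    skew_direction = if (length(fractions) > 0) {
      if (mean(fractions) < ref_mean) "A/T-skewed" else "G/C-skewed"
    } else NA_character_
  ), class = "SpacerGCReport")
}

#' @export
print.SpacerGCReport <- function(x, ...) {
  cat(sprintf(
    "SpacerGCReport: %d sites (%d excluded), mean G/C %.3f (%s), KS %.3f\n",
    x$n_sites, x$n_excluded, x$mean_gc, x$skew_direction, x$ks_statistic))
  invisible(x)
}
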