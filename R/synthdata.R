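#' @title Seeded synthetic-data generators
#'
#' @description Generators producing inputs with the statistical structure
#' each analysis stage assumes: SELEX read libraries under selection for
#' dimer sites with flexible spacers, EMSA lane intensities from the
#' two-site equilibrium, one-site ITC isotherms, and toy bent protein-DNA
#' complexes for the dimer modeler. Every generator is a pure function of
#' its arguments: the seed is mandatory and identical calls give identical
#' output.
#' @name synthdata
NULL

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

implant_site <- function(read, sites) {
  half <- sites$half_site
  spacer <- paste(sample(c("A", "C", "G", "T"), sites$spacer_length,
                         replace = TRUE), collapse = "")
  site <- paste0(half, spacer, half)
  L <- nchar(site)
  if (nchar(read) < L) return(read)
  off <- sample.int(nchar(read) - L + 1, 1)
  paste0(substr(read, 1, off - 1), site, substr(read, off + L, nchar(read)))
}

#' Simulate SELEX selection cycles
#'
#' Cycle 0 is a random background library in which a fraction of reads
#' carry a head-to-tail dimer site with uniform spacer composition. Each
#' subsequent cycle resamples reads (with replacement) with probability
#' proportional to exp(selection_strength x binding energy), where the
#' energy is the normalized best PWM log-odds score plus a linear
#' spacer-flexibility bonus for the A/T content of the analyzed spacer
#' positions of the best dimer hit. Selection strength 0 therefore gives
#' uniform resampling (a null), and larger strengths enrich A/T-spacer
#' sites faster.
#'
#' @param seed integer seed (mandatory).
#' @param n_cycles selection cycles after the initial library.
#' @param n_reads reads per cycle.
#' @param read_length read length, nt.
#' @param site_fraction fraction of cycle-0 reads carrying a dimer site.
#' @param selection_strength selection pressure (0 = none).
#' @param flex_bonus weight of the spacer A/T-fraction bonus relative to
#'   the normalized PWM score.
#' @param pwm dimer `MotifMatrix` used as the binding model.
#' @param sites a `DimerSiteDefinition`.
#' @return named list `cycle0` .. `cycleN` of data.frames (`id`,
#'   `sequence`), writable with [write_reads()].
#' @export
gen_selex <- function(seed, n_cycles = 4, n_reads = 2000, read_length = 26,
                      site_fraction = 0.1, selection_strength = 6,
                      flex_bonus = 1, pwm = dimer_pwm(),
                      sites = dimer_site()) {
  stopifnot(n_reads > 0, read_length >= motif_length(pwm), n_cycles >= 1)
  withr::with_seed(seed, {
    reads <- random_dna(n_reads, read_length)
    with_site <- which(stats::runif(n_reads) < site_fraction)
    for (i in with_site) reads[i] <- implant_site(reads[i], sites)
    lw <- log_odds_matrix(pwm)
    smax <- max_score(pwm)
    pos_spacer <- spacer_motif_positions(sites)[sites$analyzed_spacer_positions]
    L <- motif_length(pwm)
    energy <- function(s) {
      enc <- encode_dna(s); enc_rc <- encode_dna(revcomp(s))
      h <- best_hit(enc, enc_rc, lw)
      e <- h$score / smax
      if (h$score >= 0.7 * smax) {
        oriented <- if (h$strand == "+") toupper(s) else revcomp(s)
        hit_seq <- substr(oriented, h$start, h$start + L - 1)
        bases <- strsplit(hit_seq, "")[[1]][pos_spacer]
        e <- e + flex_bonus * mean(bases %in% c("A", "T"))
      }
      e
    }
    out <- list(cycle0 = data.frame(
      id = sprintf("c0_r%05d", seq_len(n_reads)), sequence = reads,
      stringsAsFactors = FALSE))
    for (cyc in seq_len(n_cycles)) {
      w <- exp(selection_strength * vapply(reads, energy, numeric(1)))
      reads <- sample(reads, n_reads, replace = TRUE, prob = w)
      out[[paste0("cycle", cyc)]] <- data.frame(
        id = sprintf("c%d_r%05d", cyc, seq_len(n_reads)), sequence = reads,
        stringsAsFactors = FALSE)
    }
    out
  })
}

#' Simulate EMSA lane intensities
#'
#' Lane species come from the two-identical-site equilibrium
#' ([species_equilibrium()]); band signals are proportional to [D], [PD]
#' and [P2D] with multiplicative Gaussian noise and an additive shifted
#' band background (applied to the monomer and dimer bands, where the
#' background correction of the tau statistic operates).
#'
#' @param seed integer seed.
#' @param Kd_site per-site dissociation constant, nM.
#' @param omega cooperativity factor.
#' @param protein_nM per-lane protein concentrations (one 0 nM background
#'   lane required).
#' @param probe_nM probe concentration, nM.
#' @param noise_cv multiplicative Gaussian noise CV on each band.
#' @param background additive background signal on the monomer and dimer
#'   bands (signal units).
#' @param signal_scale fluorescence units per nM.
#' @return an `IntensityTable`.
#' @export
gen_emsa <- function(seed, Kd_site = 30, omega = 38,
                     protein_nM = c(0, 25, 100, 400), probe_nM = 35,
                     noise_cv = 0.1, background = 0.02 * probe_nM,
                     signal_scale = 100) {
  stopifnot(sum(protein_nM == 0) == 1)
  withr::with_seed(seed, {
    rows <- lapply(seq_along(protein_nM), function(i) {
      P <- protein_nM[i]
      sp <- species_equilibrium(Kd_site, omega, P, probe_nM)
      noisy <- function(x) x * (1 + noise_cv * stats::rnorm(1))
      data.frame(
        lane = i, protein_nM = P,
        free = max(0, noisy(sp$D_free * signal_scale)),
        monomer = max(0, noisy(sp$PD * signal_scale) + background * signal_scale),
        dimer = max(0, noisy(sp$P2D * signal_scale) + background * signal_scale)
      )
    })
    as_intensity_table(do.call(rbind, rows), probe_nM = probe_nM)
  })
}

#' Simulate a one-site ITC isotherm
#'
#' Heats from [one_site_heats()] plus optional Gaussian noise.
#'
#' @param seed integer seed.
#' @param protocol a `TitrationProtocol`.
#' @param K association constant, 1/M.
#' @param dH enthalpy, kcal/mol.
#' @param n stoichiometry.
#' @param noise_ucal_sd Gaussian noise sd on each injection heat, microcal.
#' @return an `Isotherm`.
#' @export
gen_itc <- function(seed, protocol = titration_protocol(), K = 6.8e7,
                    dH = -5.4, n = 1.02, noise_ucal_sd = 0) {
  withr::with_seed(seed, {
    iso <- one_site_heats(protocol, K, dH, n)
    if (noise_ucal_sd > 0) {
      iso <- isotherm_from_heats(
        protocol,
        iso$heat_ucal + stats::rnorm(length(iso$heat_ucal), 0, noise_ucal_sd))
    }
    iso
  })
}

# interpolated base-pair frame at fractional level t (1-based)
frame_at_level <- function(H, steps, t) {
  i <- max(1, min(length(H) - 1, floor(t)))
  frac <- t - i
  Hi <- H[[i]]
  if (abs(frac) > 1e-12) {
    p <- steps[i, , drop = FALSE] * frac
    Hi <- Hi %*% step_transform(p)
  }
  Hi
}

#' Build a toy bent protein-DNA complex
#'
#' A duplex with a single TAAT core and a prescribed helical-axis bend
#' (applied as roll at the step just 5' of the core, where the
#' minor-groove-tracking arm of a homeodomain sits), plus a rigid
#' geometry-only dummy protomer: a shell of pseudo-atoms hugging the
#' major-groove face of the core footprint. The protomer exists to
#' exercise contact/clash logic in dimer models, not to be a protein.
#'
#' @param bend_deg requested DNA bend, degrees (error above 60: a short
#'   duplex cannot absorb more without unphysical backbone geometry).
#' @param sequence sense sequence; must contain exactly one TAAT.
#' @param span_levels protomer footprint relative to the core start
#'   (levels, fractional allowed).
#' @param radius_range radial shell of the protomer, Angstrom from the
#'   helix axis.
#' @param azimuth_deg azimuthal half-width of the shell around the
#'   major-groove direction.
#' @param bend_roll_sign sign of the kink roll (+1 bends the helix toward
#'   the protomer face, the arrangement that permits protomer contact).
#' @return a `Structure`: protein chain A (one CA pseudo-atom per
#'   residue), DNA chains C (sense) and D (antisense). The protomer-DNA
#'   minimum distance is within contact range and the realized bend
#'   matches `bend_deg` within 1 degree.
#' @export
gen_toy_complex <- function(bend_deg = 20, sequence = "GCGCGGTAATCCGAGCGA",
                            span_levels = c(-2.0, 6.8),
                            radius_range = c(11, 13.5),
                            azimuth_deg = 90, bend_roll_sign = 1) {
  if (bend_deg > 60) stop("requested bend > 60 degrees over a short duplex ",
                          "is unphysical")
  chars <- validate_dna_sequence(sequence)
  n <- length(chars)
  core <- regexpr("TAAT", sequence)[1]
  if (core < 4) stop("sequence must contain TAAT after position 3")
  steps <- ideal_step()[rep(1, n - 1), , drop = FALSE]
  # kink just upstream of the protomer footprint (the arm region)
  steps$roll[core - 3] <- bend_roll_sign * bend_deg
  duplex <- build_duplex(sequence, steps = steps)
  dna <- duplex$structure$atoms
  dna$chain <- ifelse(dna$chain == "A", "C", "D")

  H <- frames_from_steps(steps)
  levels <- seq(span_levels[1], span_levels[2], by = 0.8)
  azim <- seq(-azimuth_deg, azimuth_deg, by = 30) * pi / 180
  rows <- list()
  resno <- 0
  for (t in levels) {
    Ht <- frame_at_level(H, steps, core + t)
    R <- hrot(Ht); o <- horg(Ht)
    for (r in radius_range) for (ps in azim) {
      resno <- resno + 1
      local <- c(r * cos(ps), r * sin(ps), 0)
      xyz <- as.numeric(R %*% local + o)
      rows[[resno]] <- data.frame(
        serial = resno, name = "CA", resname = "GLY", chain = "A",
        resno = resno, x = xyz[1], y = xyz[2], z = xyz[3],
        element = "C", occ = 1, b = 0, stringsAsFactors = FALSE)
    }
  }
  prot <- do.call(rbind, rows)
  dna$serial <- dna$serial + nrow(prot)
  new_structure(rbind(prot, dna), metadata = list(
    toy = TRUE, bend_deg = bend_deg, core_start = core,
    source = "gen_toy_complex"))
}
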