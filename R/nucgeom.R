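#' @title Nucleic-acid geometry
#'
#' @description Base-pair reference frames, rigid-body step parameters
#' (shift, slide, rise, tilt, roll, twist; mid-step convention), B-DNA
#' construction from ideal, sequence-dependent or explicit step parameters,
#' global helical-axis bend, groove geometry and sequence-based shape
#' features. Angles are degrees, distances Angstrom.
#' @name nucgeom
NULL

FLIP_COMPLEMENT <- diag(c(1, -1, -1))  # 180 deg about x: maps the paired base

validate_dna_sequence <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) < 2) stop("sequence must have length >= 2")
  bad <- setdiff(unique(chars), c("A", "C", "G", "T"))
  if (length(bad) > 0) stop("non-ACGT character(s): ", paste(bad, collapse = ", "))
  chars
}

revcomp <- function(sequence) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(sequence), "")[[1]]]), collapse = "")
}

ideal_step <- function() {
  data.frame(shift = 0, slide = 0, rise = IDEAL_B_RISE,
             tilt = 0, roll = 0, twist = IDEAL_B_TWIST)
}

# Relative transform of frame i+1 expressed in frame i, mid-step (CEHS /
# 3DNA style) convention: rotation Rz(W/2 - phi) Ry(Gamma) Rz(W/2 + phi)
# with Gamma = sqrt(tilt^2 + roll^2), phi = atan2(tilt, roll); the
# translation (shift, slide, rise) is expressed in the mid-step frame.
step_transform <- function(p) {
  gam <- deg2rad(sqrt(p$tilt^2 + p$roll^2))
  phi <- atan2(p$tilt, p$roll)
  omega <- deg2rad(p$twist)
  a <- omega / 2 - phi
  b <- omega / 2 + phi
  R <- rot_z(a) %*% rot_y(gam) %*% rot_z(b)
  Rm <- rot_z(a) %*% rot_y(gam / 2) %*% rot_z(phi)
  t <- Rm %*% c(p$shift, p$slide, p$rise)
  hmat(R, as.numeric(t))
}

# Exact inverse of step_transform: ZYZ factorization of the relative
# rotation, translation read off in the mid-step frame.
step_from_transform <- function(Q, dvec) {
  singam <- sqrt(Q[1, 3]^2 + Q[2, 3]^2)
  gam <- atan2(singam, Q[3, 3])
  if (singam < 1e-9) {
    omega <- atan2(Q[2, 1], Q[1, 1])
    phi <- 0
    gam <- 0
  } else {
    a <- atan2(Q[2, 3], Q[1, 3])
    b <- atan2(Q[3, 2], -Q[3, 1])
    # keep the twist on the principal branch: the (a - pi, b - pi, -Gamma)
    # parameterization generates the identical transform
    if (a + b > pi) { a <- a - pi; b <- b - pi; gam <- -gam }
    if (a + b <= -pi) { a <- a + pi; b <- b + pi; gam <- -gam }
    omega <- a + b
    phi <- (b - a) / 2
  }
  Rm <- rot_z(omega / 2 - phi) %*% rot_y(gam / 2) %*% rot_z(phi)
  tr <- as.numeric(t(Rm) %*% dvec)
  data.frame(shift = tr[1], slide = tr[2], rise = tr[3],
             tilt = rad2deg(gam * sin(phi)),
             roll = rad2deg(gam * cos(phi)),
             twist = rad2deg(omega))
}

resolve_steps <- function(chars, step_model, steps) {
  n <- length(chars)
  if (!is.null(steps)) step_model <- "explicit"
  if (step_model == "explicit") {
    if (is.null(steps)) stop("explicit step model requires a steps table")
    steps <- as.data.frame(steps)
    need <- c("shift", "slide", "rise", "tilt", "roll", "twist")
    if (!all(need %in% names(steps))) {
      stop("steps table needs columns ", paste(need, collapse = ", "))
    }
    if (nrow(steps) != n - 1) {
      stop("need ", n - 1, " steps for a ", n, "-mer, got ", nrow(steps))
    }
    if (any(steps$rise <= 0)) stop("rise must be positive")
    return(steps[, need])
  }
  if (step_model == "ideal_b") {
    return(ideal_step()[rep(1, n - 1), , drop = FALSE])
  }
  tab <- load_step_table()
  dinucs <- paste0(chars[-n], chars[-1])
  out <- tab[dinucs, c("shift", "slide", "rise", "tilt", "roll", "twist")]
  rownames(out) <- NULL
  out
}

frames_from_steps <- function(steps) {
  n <- nrow(steps) + 1
  H <- vector("list", n)
  H[[1]] <- diag(4)
  for (i in seq_len(n - 1)) {
    H[[i + 1]] <- H[[i]] %*% step_transform(steps[i, , drop = FALSE])
  }
  H
}

#' Build a double-stranded B-DNA model
#'
#' Places rigid standard-geometry nucleotides (base heavy atoms, C1' and a
#' phosphate per residue, with bridging O3') on a run of base-pair frames
#' generated from step parameters. `ideal_b` uses twist 36.0 degrees and
#' rise 3.38 Angstrom with all other parameters zero; `sequence_dependent`
#' uses the bundled dinucleotide survey table; an explicit `steps` table
#' overrides both.
#'
#' @param sequence sense-strand DNA text (ACGT), length >= 2.
#' @param step_model `"ideal_b"` or `"sequence_dependent"`.
#' @param steps optional explicit step-parameter data.frame
#'   (`shift, slide, rise, tilt, roll, twist`), one row per step.
#' @return a `DuplexStructure` (sense chain A, antisense chain B).
#' @export
build_duplex <- function(sequence, step_model = c("ideal_b", "sequence_dependent"),
                         steps = NULL) {
  step_model <- if (!is.null(steps)) "explicit" else match.arg(step_model)
  chars <- validate_dna_sequence(sequence)
  n <- length(chars)
  steps <- resolve_steps(chars, step_model, steps)
  H <- frames_from_steps(steps)
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  rows <- list()
  serial <- 0
  p_sense <- matrix(NA_real_, n, 3)
  p_anti <- matrix(NA_real_, n, 3)
  add_atom <- function(name, xyz, chain, resno, resname) {
    serial <<- serial + 1
    el <- if (name == "P") "P" else substr(name, 1, 1)
    rows[[length(rows) + 1]] <<- data.frame(
      serial = serial, name = name, resname = resname, chain = chain,
      resno = resno, x = xyz[1], y = xyz[2], z = xyz[3],
      element = el, occ = 1, b = 0, stringsAsFactors = FALSE)
  }

  for (i in seq_len(n)) {
    R <- hrot(H[[i]]); o <- horg(H[[i]])
    place <- function(local) as.numeric(R %*% local + o)
    sb <- chars[i]
    std <- STD_BASE_COORDS[[sb]]
    p_sense[i, ] <- place(P_LOCAL)
    add_atom("P", p_sense[i, ], "A", i, paste0("D", sb))
    for (an in rownames(std)) {
      add_atom(an, place(std[an, ]), "A", i, paste0("D", sb))
    }
    ab <- comp[sb]
    stda <- STD_BASE_COORDS[[ab]]
    aresno <- n + 1 - i  # antisense residue numbering runs 5'->3'
    p_anti[i, ] <- place(FLIP_COMPLEMENT %*% P_LOCAL)
    add_atom("P", p_anti[i, ], "B", aresno, paste0("D", ab))
    for (an in rownames(stda)) {
      add_atom(an, place(FLIP_COMPLEMENT %*% stda[an, ]), "B", aresno,
               paste0("D", ab))
    }
  }

  # bridging O3': on the P(i) -> P(i+1) segment, 1.6 A from the downstream P
  o3_on <- function(p_from, p_to) p_to + 1.6 * unit(p_from - p_to)
  Hn_ext <- H[[n]] %*% step_transform(utils::tail(steps, 1))
  H1_ext <- H[[1]] %*% solve(step_transform(steps[1, , drop = FALSE]))
  p_sense_next <- as.numeric(hrot(Hn_ext) %*% P_LOCAL + horg(Hn_ext))
  p_anti_prev <- as.numeric(hrot(H1_ext) %*% (FLIP_COMPLEMENT %*% P_LOCAL) +
                              horg(H1_ext))
  for (i in seq_len(n)) {
    nxt <- if (i < n) p_sense[i + 1, ] else p_sense_next
    add_atom("O3'", o3_on(p_sense[i, ], nxt), "A", i, paste0("D", chars[i]))
    # antisense residue at level i runs toward decreasing level
    nxt_a <- if (i > 1) p_anti[i - 1, ] else p_anti_prev
    add_atom("O3'", o3_on(p_anti[i, ], nxt_a), "B", n + 1 - i,
             paste0("D", comp[chars[i]]))
  }

  atoms <- do.call(rbind, rows)
  struct <- new_structure(atoms, metadata = list(
    built = TRUE, step_model = step_model, sequence = paste(chars, collapse = "")))
  structure(list(
    structure = struct,
    sense_chain = "A", anti_chain = "B",
    sense_resno = seq_len(n), anti_resno = seq_len(n),
    sense_sequence = paste(chars, collapse = ""),
    antisense_sequence = revcomp(paste(chars, collapse = "")),
    pairing = data.frame(sense_idx = seq_len(n), anti_idx = rev(seq_len(n))),
    overhangs = list(sense = integer(0), antisense = integer(0))
  ), class = "DuplexStructure")
}

fit_base_frame <- function(structure, chain, resno, base, flip = FALSE) {
  std <- STD_BASE_COORDS[[base]]
  ring <- base_ring_atom_names(base)
  obs <- residue_atom_xyz(structure, chain, resno, ring)
  if (is.null(obs)) return(NULL)
  fit <- kabsch(std[ring, , drop = FALSE], obs)
  R <- fit$rotation
  if (flip) R <- R %*% FLIP_COMPLEMENT
  list(R = R, origin = fit$translation, fit_rmsd = fit$rmsd)
}

#' Base-pair reference frames of a duplex
#'
#' Each base is least-squares superposed onto the bundled standard
#' geometry; the pair frame is the orthonormal average of the sense frame
#' and the complement-flipped antisense frame. Pairs with missing base
#' ring atoms are flagged (`ok = FALSE`) and excluded downstream.
#'
#' @param duplex a `DuplexStructure`.
#' @return list of frames: each `list(origin, R, ok)` with `R` columns =
#'   (x toward major groove, y toward sense backbone, z along helix).
#' @export
base_pair_frames <- function(duplex) {
  s <- duplex$structure
  sseq <- strsplit(duplex$sense_sequence, "")[[1]]
  aseq <- strsplit(duplex$antisense_sequence, "")[[1]]
  frames <- vector("list", nrow(duplex$pairing))
  for (k in seq_len(nrow(duplex$pairing))) {
    si <- duplex$pairing$sense_idx[k]
    ai <- duplex$pairing$anti_idx[k]
    sb <- sseq[si]; ab <- aseq[ai]
    if (sb == "N" || ab == "N") { frames[[k]] <- list(ok = FALSE); next }
    fs <- fit_base_frame(s, duplex$sense_chain, duplex$sense_resno[si], sb)
    fa <- fit_base_frame(s, duplex$anti_chain, duplex$anti_resno[ai], ab,
                         flip = TRUE)
    if (is.null(fs) || is.null(fa)) { frames[[k]] <- list(ok = FALSE); next }
    R <- orthonormalize_rotation(fs$R + fa$R)
    frames[[k]] <- list(origin = (fs$origin + fa$origin) / 2, R = R, ok = TRUE)
  }
  frames
}

check_frame <- function(f) {
  if (!isTRUE(f$ok)) stop("frame flagged as unusable")
  if (max(abs(t(f$R) %*% f$R - diag(3))) > 1e-6) {
    stop("non-orthonormal base-pair frame")
  }
}

#' Rigid-body step parameters between consecutive base-pair frames
#'
#' Mid-step-frame convention: parameters are extracted from the relative
#' rotation/translation of consecutive frames; angles in degrees. Exact
#' inverse of the transform used by [build_duplex()] with explicit steps.
#'
#' @param frames frame list from [base_pair_frames()].
#' @return data.frame with one row per step:
#'   `shift, slide, rise, tilt, roll, twist`.
#' @export
step_parameters <- function(frames) {
  frames <- Filter(function(f) isTRUE(f$ok), frames)
  if (length(frames) < 2) stop("need at least 2 usable frames")
  out <- vector("list", length(frames) - 1)
  for (i in seq_len(length(frames) - 1)) {
    f1 <- frames[[i]]; f2 <- frames[[i + 1]]
    check_frame(f1); check_frame(f2)
    Q <- t(f1$R) %*% f2$R
    dvec <- as.numeric(t(f1$R) %*% (f2$origin - f1$origin))
    out[[i]] <- step_from_transform(Q, dvec)
  }
  do.call(rbind, out)
}

local_helical_axes <- function(frames) {
  m <- length(frames) - 1
  axes <- matrix(NA_real_, m, 3)
  for (i in seq_len(m)) {
    Q <- t(frames[[i]]$R) %*% frames[[i + 1]]$R
    ax <- rotation_axis(Q)
    if (ax[3] < 0) ax <- -ax  # orient along the advancing helix
    axes[i, ] <- as.numeric(frames[[i]]$R %*% ax)
  }
  axes
}

#' Global helical-axis bend of a duplex
#'
#' Local helical axes are the rotation axes of the frame-to-frame
#' transforms; the global bend is the angle between the mean axis over the
#' first `end_window` steps and the mean axis over the last `end_window`
#' steps, after excluding `trim_ends` terminal pairs (terminal pairs are
#' the least reliable). Per-step bend angles localize the kink.
#'
#' @param duplex a `DuplexStructure` (or a precomputed frame list).
#' @param end_window steps per end window.
#' @param trim_ends terminal pairs excluded per end.
#' @return a `BendReport`: `bend_angle` (degrees), `end_axis_1/2`,
#'   `per_step_bend`, `method_tag`.
#' @export
bend_angle <- function(duplex, end_window = 4, trim_ends = 1) {
  frames <- if (inherits(duplex, "DuplexStructure")) base_pair_frames(duplex)
  else duplex
  frames <- Filter(function(f) isTRUE(f$ok), frames)
  n <- length(frames)
  m <- n - 1  # steps
  usable <- seq_len(m)
  if (trim_ends > 0) {
    usable <- usable[usable > trim_ends & usable <= m - trim_ends]
  }
  if (length(usable) < 2 * end_window) {
    stop("end windows overlap: need >= ", 2 * end_window + 2 * trim_ends + 1,
         " base pairs, have ", n)
  }
  axes <- local_helical_axes(frames)
  w1 <- usable[seq_len(end_window)]
  w2 <- usable[seq(length(usable) - end_window + 1, length(usable))]
  a1 <- unit(colMeans(axes[w1, , drop = FALSE]))
  a2 <- unit(colMeans(axes[w2, , drop = FALSE]))
  per_step <- vapply(seq_len(m - 1), function(i)
    angle_between_deg(axes[i, ], axes[i + 1, ]), numeric(1))
  structure(list(
    bend_angle = angle_between_deg(a1, a2),
    end_axis_1 = a1, end_axis_2 = a2,
    per_step_bend = per_step,
    method_tag = sprintf("end-window mean local axes (window %d, trim %d)",
                         end_window, trim_ends)
  ), class = "BendReport")
}

#' @export
print.BendReport <- function(x, ...) {
  cat(sprintf("BendReport: %.2f degrees (%s)\n", x$bend_angle, x$method_tag))
  invisible(x)
}

phosphate_levels <- function(duplex) {
  s <- duplex$structure
  np <- nrow(duplex$pairing)
  ps <- matrix(NA_real_, np, 3)
  pa <- matrix(NA_real_, np, 3)
  for (k in seq_len(np)) {
    xs <- residue_atom_xyz(s, duplex$sense_chain,
                           duplex$sense_resno[duplex$pairing$sense_idx[k]], "P")
    xa <- residue_atom_xyz(s, duplex$anti_chain,
                           duplex$anti_resno[duplex$pairing$anti_idx[k]], "P")
    if (!is.null(xs)) ps[k, ] <- xs
    if (!is.null(xa)) pa[k, ] <- xa
  }
  list(sense = ps, anti = pa)
}

# Phosphate position at integer or half-integer level (midpoint), NA if
# out of range or missing.
p_at_level <- function(P, x) {
  n <- nrow(P)
  lo <- floor(x); hi <- ceiling(x)
  if (lo < 1 || hi > n) return(rep(NA_real_, 3))
  if (lo == hi) return(P[lo, ])
  (P[lo, ] + P[hi, ]) / 2
}

# Cross-strand register offsets (in base-pair levels) used for groove
# widths, calibrated on the ideal B-form build: the minor groove at level
# i spans the sense phosphate ~2 levels above and the antisense phosphate
# ~2 levels below i (and vice versa for the major groove).
GROOVE_MINOR_OFFSET <- 1.0
GROOVE_MAJOR_OFFSET <- -2.5

#' Groove geometry of a duplex
#'
#' Widths follow the refined phosphate-phosphate convention: cross-strand
#' P-P distance at the groove register minus 5.8 Angstrom (two phosphate
#' van der Waals radii). Depths are the distance from the P-P midpoint to
#' the base-pair origin. Levels without the needed phosphates are flagged
#' undefined (NA), never zero-filled.
#'
#' @param duplex a `DuplexStructure`.
#' @return a `GrooveProfile` data.frame: per level `minor_width`,
#'   `major_width`, `minor_depth`, `major_depth` and `defined` flags.
#' @export
groove_profile <- function(duplex) {
  P <- phosphate_levels(duplex)
  frames <- base_pair_frames(duplex)
  np <- nrow(duplex$pairing)
  out <- data.frame(level = seq_len(np),
                    minor_width = NA_real_, major_width = NA_real_,
                    minor_depth = NA_real_, major_depth = NA_real_)
  for (i in seq_len(np)) {
    org <- if (isTRUE(frames[[i]]$ok)) frames[[i]]$origin else rep(NA_real_, 3)
    s_min <- p_at_level(P$sense, i + GROOVE_MINOR_OFFSET)
    a_min <- p_at_level(P$anti, i - GROOVE_MINOR_OFFSET)
    if (!anyNA(c(s_min, a_min))) {
      out$minor_width[i] <- max(0, vnorm(s_min - a_min) - PHOSPHATE_VDW_CORRECTION)
      if (!anyNA(org)) out$minor_depth[i] <- vnorm((s_min + a_min) / 2 - org)
    }
    s_maj <- p_at_level(P$sense, i + GROOVE_MAJOR_OFFSET)
    a_maj <- p_at_level(P$anti, i - GROOVE_MAJOR_OFFSET)
    if (!anyNA(c(s_maj, a_maj))) {
      out$major_width[i] <- max(0, vnorm(s_maj - a_maj) - PHOSPHATE_VDW_CORRECTION)
      if (!anyNA(org)) out$major_depth[i] <- vnorm((s_maj + a_maj) / 2 - org)
    }
  }
  out$defined_minor <- !is.na(out$minor_width)
  out$defined_major <- !is.na(out$major_width)
  class(out) <- c("GrooveProfile", "data.frame")
  out
}

#' Sequence-based DNA shape features
#'
#' A simplified geometric shape predictor: the sequence is built with the
#' bundled sequence-dependent step table and measured. Reported per
#' position: minor groove width, propeller twist (table-driven), roll and
#' helix twist. End positions lacking full parameter context are flagged
#' undefined, never extrapolated. Deterministic for a given bundled table
#' version.
#'
#' @param sequence DNA text, length >= 5.
#' @return a `ShapeProfile` data.frame.
#' @export
predict_shape <- function(sequence) {
  chars <- validate_dna_sequence(sequence)
  n <- length(chars)
  if (n < 5) stop("sequence shorter than the 5-bp shape context")
  duplex <- build_duplex(sequence, step_model = "sequence_dependent")
  tab <- load_step_table()
  dinucs <- paste0(chars[-n], chars[-1])
  roll_step <- tab[dinucs, "roll"]
  twist_step <- tab[dinucs, "twist"]
  prop_step <- tab[dinucs, "propeller"]
  gp <- groove_profile(duplex)
  step_mean <- function(v, i) {
    # position value = mean of flanking steps; ends undefined
    if (i == 1 || i == n) return(NA_real_)
    mean(c(v[i - 1], v[i]))
  }
  out <- data.frame(
    position = seq_len(n), base = chars,
    minor_groove_width = gp$minor_width,
    propeller_twist = vapply(seq_len(n), function(i) step_mean(prop_step, i),
                             numeric(1)),
    roll = vapply(seq_len(n), function(i) step_mean(roll_step, i), numeric(1)),
    helix_twist = vapply(seq_len(n), function(i) step_mean(twist_step, i),
                         numeric(1))
  )
  out$defined <- stats::complete.cases(out[, c("minor_groove_width",
                                               "propeller_twist", "roll",
                                               "helix_twist")])
  class(out) <- c("ShapeProfile", "data.frame")
  out
}

#' Write a shape or groove profile as TSV
#' @param profile data.frame from [predict_shape()] or [groove_profile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
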