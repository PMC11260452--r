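#' @title Head-to-tail dimer modeling on spaced binding sites
#'
#' @description Builds two-protomer models on TAAT-spacer-TAAT dimer sites
#' by the trim-and-join procedure: the monomer protein-DNA complex is
#' duplicated, terminal base pairs are trimmed, and the duplicate is
#' placed so the two TAAT cores sit exactly `spacer_bp` base pairs apart -
#' either by superposing overlapping junction base-pair frames (preserving
#' the monomer's DNA bend) or on a freshly built ideal straight B-form
#' duplex. No internal coordinates of either protomer or of the retained
#' DNA are altered; only the junction backbone is rebuilt.
#' @name dimermodel
NULL

O3P_MIN <- 1.3
O3P_MAX <- 1.9

# Split a complex into its single protein chain and its duplex chains;
# the sense strand is the one carrying the TAAT core.
complex_parts <- function(structure) {
  chains <- structure_chains(strip_waters(structure))
  nuc <- chains[vapply(chains, function(ch) is_nucleic_chain(structure, ch),
                       logical(1))]
  prot <- setdiff(chains, nuc)
  if (length(nuc) != 2) stop("complex must contain exactly one duplex ",
                             "(two nucleic chains); found ", length(nuc))
  if (length(prot) != 1) stop("complex must contain exactly one protein ",
                              "chain; found ", length(prot))
  duplex <- extract_duplex(structure, nuc)
  if (!grepl("TAAT", duplex$sense_sequence)) {
    duplex2 <- extract_duplex(structure, rev(nuc))
    if (grepl("TAAT", duplex2$sense_sequence)) duplex <- duplex2
  }
  list(protein_chain = prot, duplex = duplex)
}

duplex_level_residues <- function(duplex) {
  data.frame(
    level = seq_len(nrow(duplex$pairing)),
    sense_resno = duplex$sense_resno[duplex$pairing$sense_idx],
    anti_resno = duplex$anti_resno[duplex$pairing$anti_idx]
  )
}

#' Trim terminal base pairs from a complex's duplex
#'
#' Removes base pairs symmetrically from both strands at the duplex ends;
#' the protein is untouched. Refuses to delete any nucleotide whose heavy
#' atoms lie within 4.5 Angstrom of the protein (the protein-contacted
#' footprint).
#'
#' @param complex a `Structure` with one protein chain and one duplex.
#' @param n_remove_5prime,n_remove_3prime base pairs to remove from the
#'   5' / 3' end of the sense strand.
#' @return trimmed `Structure`.
#' @export
trim_duplex <- function(complex, n_remove_5prime, n_remove_3prime) {
  if (n_remove_5prime == 0 && n_remove_3prime == 0) return(complex)
  parts <- complex_parts(complex)
  lv <- duplex_level_residues(parts$duplex)
  n <- nrow(lv)
  if (n - n_remove_5prime - n_remove_3prime < 1) {
    stop("trim would leave no base pairs")
  }
  drop <- c(utils::head(seq_len(n), n_remove_5prime),
            utils::tail(seq_len(n), n_remove_3prime))
  a <- complex$atoms
  prot <- heavy_atoms(subset_structure(complex,
                                       a$chain == parts$protein_chain))
  pm <- coords(prot)
  dup <- parts$duplex
  drop_keys <- character(0)
  for (i in drop) {
    for (side in c("sense", "anti")) {
      ch <- if (side == "sense") dup$sense_chain else dup$anti_chain
      rn <- if (side == "sense") lv$sense_resno[i] else lv$anti_resno[i]
      sel <- a$chain == ch & a$resno == rn & toupper(a$element) != "H"
      xyz <- as.matrix(a[sel, c("x", "y", "z")])
      d2 <- outer(rowSums(xyz^2), rowSums(pm^2), `+`) - 2 * xyz %*% t(pm)
      if (min(d2) <= 4.5^2) {
        stop("trim would delete protein-contacting nucleotide ",
             ch, ":", rn, " (within 4.5 A of protein)")
      }
      drop_keys <- c(drop_keys, paste(ch, rn))
    }
  }
  keep <- !(paste(a$chain, a$resno) %in% drop_keys)
  subset_structure(complex, keep)
}

frame_points <- function(frame, scale = 5) {
  rbind(frame$origin,
        frame$origin + scale * frame$R[, 1],
        frame$origin + scale * frame$R[, 2],
        frame$origin + scale * frame$R[, 3])
}

# Relabel a chain and renumber residues, preserving atom order.
relabel <- function(atoms, chain_from, new_chain, resno_map = NULL) {
  sel <- atoms$chain == chain_from
  out <- atoms[sel, , drop = FALSE]
  if (!is.null(resno_map)) {
    out <- out[out$resno %in% as.integer(names(resno_map)), , drop = FALSE]
    out$resno <- resno_map[as.character(out$resno)]
  }
  out$chain <- new_chain
  out
}

ensure_o3_bridge <- function(atoms, chain, resno, p_cur, p_next) {
  xyz <- p_next + 1.6 * unit(p_cur - p_next)
  sel <- atoms$chain == chain & atoms$resno == resno & atoms$name == "O3'"
  if (any(sel)) {
    atoms$x[sel] <- xyz[1]; atoms$y[sel] <- xyz[2]; atoms$z[sel] <- xyz[3]
  } else {
    row <- atoms[atoms$chain == chain & atoms$resno == resno, , drop = FALSE][1, ]
    row$name <- "O3'"; row$element <- "O"
    row$x <- xyz[1]; row$y <- xyz[2]; row$z <- xyz[3]
    row$serial <- max(atoms$serial) + 1
    atoms <- rbind(atoms, row)
  }
  atoms
}

p_of <- function(atoms, chain, resno) {
  sel <- atoms$chain == chain & atoms$resno == resno & atoms$name == "P"
  if (!any(sel)) return(NULL)
  as.numeric(atoms[which(sel)[1], c("x", "y", "z")])
}

o3_of <- function(atoms, chain, resno) {
  sel <- atoms$chain == chain & atoms$resno == resno & atoms$name == "O3'"
  if (!any(sel)) return(NULL)
  as.numeric(atoms[which(sel)[1], c("x", "y", "z")])
}

#' Join a duplicated monomer complex into a head-to-tail dimer model
#'
#' The monomer complex is duplicated and the copy placed downstream so the
#' two TAAT cores (same strand, 5'->3') are separated by exactly
#' `spacer_bp` base pairs. `preserve_bend` superposes a 2-base-pair
#' overlap window of duplicate base-pair frames onto the original's
#' terminal frames, keeping the monomer's DNA bend in each half;
#' `ideal_b` rebuilds the full-length DNA as an ideal straight B-form
#' duplex and docks both protomers onto it by their core frames. The
#' junction backbone is rebuilt to valid O3'-P geometry; nothing else
#' moves.
#'
#' @param monomer_complex `Structure`: one protein chain + one duplex with
#'   a TAAT core on the sense strand.
#' @param spacer_bp spacer length between the cores, bp (>= 0).
#' @param bend_mode `"preserve_bend"` or `"ideal_b"`.
#' @param frame_tol maximum junction frame-superposition rmsd, Angstrom.
#' @return a `DimerModel`: composite `Structure` (protein chains A and B,
#'   DNA chains C and D), `spacer_bp`, `bend_mode`, provenance.
#' @export
join_as_dimer <- function(monomer_complex, spacer_bp,
                          bend_mode = c("preserve_bend", "ideal_b"),
                          frame_tol = 1.5) {
  bend_mode <- match.arg(bend_mode)
  stopifnot(spacer_bp >= 0)
  parts <- complex_parts(monomer_complex)
  dup <- parts$duplex
  lv <- duplex_level_residues(dup)
  N <- nrow(lv)
  frames <- base_pair_frames(dup)
  if (!all(vapply(frames, function(f) isTRUE(f$ok), logical(1)))) {
    stop("duplex has unusable base-pair frames")
  }
  core_in_seq <- regexpr("TAAT", dup$sense_sequence)[1]
  if (core_in_seq < 0) stop("no TAAT core on the sense strand")
  core_level <- match(core_in_seq, dup$pairing$sense_idx)
  if (is.na(core_level)) stop("TAAT core falls outside the paired region")
  k <- 4 + spacer_bp  # level offset between the two core starts
  if (N < k + 2) {
    stop("duplex too short for a ", spacer_bp, "-bp spacer: need >= ",
         k + 2, " base pairs for the 2-bp junction overlap, have ", N)
  }
  a <- monomer_complex$atoms
  total <- N + k
  sense_seq <- strsplit(dup$sense_sequence, "")[[1]][dup$pairing$sense_idx]

  if (bend_mode == "preserve_bend") {
    # The junction sits just downstream of the original's core region:
    # the copy's first two base-pair frames are superposed onto the
    # original's frames at levels (k+1, k+2), so the composite keeps the
    # original DNA through level j = k+2 and the copy DNA (with its own
    # bend around its core) beyond. Each half therefore carries the
    # monomer's bend unchanged.
    j <- k + 2
    src <- rbind(frame_points(frames[[1]]), frame_points(frames[[2]]))
    dst <- rbind(frame_points(frames[[k + 1]]), frame_points(frames[[k + 2]]))
    fit <- kabsch(src, dst)
    if (fit$rmsd > frame_tol) {
      stop(sprintf(paste0("junction geometry unsatisfiable: overlap-frame ",
                          "rmsd %.2f A exceeds tolerance %.2f A"),
                   fit$rmsd, frame_tol))
    }
    copy_atoms <- a
    xyz <- apply_rigid(as.matrix(a[, c("x", "y", "z")]),
                       fit$rotation, fit$translation)
    copy_atoms$x <- xyz[, 1]; copy_atoms$y <- xyz[, 2]; copy_atoms$z <- xyz[, 3]

    prot_a <- relabel(a, parts$protein_chain, "A")
    prot_b <- relabel(copy_atoms, parts$protein_chain, "B")
    # DNA: original levels 1..j, then copy levels 3..N as j+1..N+k
    orig_lv <- seq_len(j)
    smap1 <- stats::setNames(orig_lv, lv$sense_resno[orig_lv])
    sense1 <- relabel(a, dup$sense_chain, "C", smap1)
    keep_lv <- seq(3, N)
    smap2 <- stats::setNames(keep_lv + k, lv$sense_resno[keep_lv])
    sense2 <- relabel(copy_atoms, dup$sense_chain, "C", smap2)
    amap1 <- stats::setNames(total + 1 - orig_lv, lv$anti_resno[orig_lv])
    anti1 <- relabel(a, dup$anti_chain, "D", amap1)
    amap2 <- stats::setNames(total + 1 - (keep_lv + k), lv$anti_resno[keep_lv])
    anti2 <- relabel(copy_atoms, dup$anti_chain, "D", amap2)
    dna <- rbind(sense1, sense2, anti1, anti2)
    junction_levels <- j  # sense C resno j -> j+1; anti D between same levels
  } else {
    # rebuild the whole DNA as an ideal straight duplex, dock both protomers
    comp_seq <- c(sense_seq, sense_seq[seq(N - k + 1, N)])
    ideal <- build_duplex(paste(comp_seq, collapse = ""))
    iframes <- base_pair_frames(ideal)
    place_protein <- function(core_target) {
      src <- rbind(frame_points(frames[[core_level]]),
                   frame_points(frames[[core_level + 1]]))
      dst <- rbind(frame_points(iframes[[core_target]]),
                   frame_points(iframes[[core_target + 1]]))
      fit <- kabsch(src, dst)
      pa <- a[a$chain == parts$protein_chain, , drop = FALSE]
      xyz <- apply_rigid(as.matrix(pa[, c("x", "y", "z")]),
                         fit$rotation, fit$translation)
      pa$x <- xyz[, 1]; pa$y <- xyz[, 2]; pa$z <- xyz[, 3]
      pa
    }
    prot_a <- place_protein(core_level); prot_a$chain <- "A"
    prot_b <- place_protein(core_level + k); prot_b$chain <- "B"
    dna <- ideal$structure$atoms
    dna$chain <- ifelse(dna$chain == "A", "C", "D")
    junction_levels <- integer(0)  # continuous by construction
  }

  all_atoms <- rbind(prot_a, prot_b, dna)
  all_atoms$serial <- seq_len(nrow(all_atoms))

  if (length(junction_levels) > 0) {
    jl <- junction_levels
    # sense strand: O3'(level jl) bridges to P(level jl+1)
    p_cur <- p_of(all_atoms, "C", jl)
    p_next <- p_of(all_atoms, "C", jl + 1)
    if (!is.null(p_cur) && !is.null(p_next)) {
      all_atoms <- ensure_o3_bridge(all_atoms, "C", jl, p_cur, p_next)
    }
    # antisense runs 3'->5' with level: O3' of residue at level jl+1
    # bridges to P at level jl (anti resno total-level+1)
    ar_hi <- total - jl      # anti resno at level jl + 1
    ar_lo <- total - jl + 1  # anti resno at level jl
    p_cur <- p_of(all_atoms, "D", ar_hi)
    p_next <- p_of(all_atoms, "D", ar_lo)
    if (!is.null(p_cur) && !is.null(p_next)) {
      all_atoms <- ensure_o3_bridge(all_atoms, "D", ar_hi, p_cur, p_next)
    }
  }

  model_struct <- new_structure(all_atoms, metadata = list(
    dimer_model = TRUE, spacer_bp = spacer_bp, bend_mode = bend_mode,
    source = monomer_complex$metadata$source))

  # DNA-DNA overlap guard across the junction (preserve_bend only; the
  # ideal_b DNA is continuous by construction)
  if (length(junction_levels) > 0) {
    j <- junction_levels
    at <- model_struct$atoms
    dna_new <- at$chain %in% c("C", "D")
    half1 <- at[dna_new & ((at$chain == "C" & at$resno <= j - 2) |
                           (at$chain == "D" & at$resno > total - j + 2)), ]
    half2 <- at[dna_new & ((at$chain == "C" & at$resno > j + 2) |
                           (at$chain == "D" & at$resno <= total - j - 2)), ]
    if (nrow(half1) > 0 && nrow(half2) > 0) {
      m1 <- as.matrix(half1[, c("x", "y", "z")])
      m2 <- as.matrix(half2[, c("x", "y", "z")])
      d2 <- outer(rowSums(m1^2), rowSums(m2^2), `+`) - 2 * m1 %*% t(m2)
      if (min(d2) < 1) stop("spacer too short: duplicated DNA halves overlap")
    }
  }

  structure(list(
    structure = model_struct, spacer_bp = spacer_bp, bend_mode = bend_mode,
    n_bp = total, core_levels = c(core_level, core_level + k),
    provenance = list(source = monomer_complex$metadata$source,
                      overlap_levels = if (bend_mode == "preserve_bend")
                        c(k + 1, k + 2) else NULL)
  ), class = "DimerModel")
}

#' @export
print.DimerModel <- function(x, ...) {
  cat(sprintf("DimerModel: %d-bp spacer, %s, %d bp DNA, cores at %d/%d\n",
              x$spacer_bp, x$bend_mode, x$n_bp,
              x$core_levels[1], x$core_levels[2]))
  invisible(x)
}

#' Check duplex backbone continuity of a model
#'
#' Every consecutive O3'-P pair along each strand must fall within
#' 1.3-1.9 Angstrom (where both atoms exist).
#'
#' @param model a `DimerModel`.
#' @return TRUE, or a character vector describing violations.
#' @export
junction_continuity <- function(model) {
  atoms <- model$structure$atoms
  bad <- character(0)
  for (ch in c("C", "D")) {
    resnos <- sort(unique(atoms$resno[atoms$chain == ch]))
    for (i in seq_len(length(resnos) - 1)) {
      o3 <- o3_of(atoms, ch, resnos[i])
      p <- p_of(atoms, ch, resnos[i + 1])
      if (is.null(o3) || is.null(p)) next
      d <- vnorm(o3 - p)
      if (d < O3P_MIN || d > O3P_MAX) {
        bad <- c(bad, sprintf("%s:%d-%d O3'-P %.2f A", ch, resnos[i],
                              resnos[i + 1], d))
      }
    }
  }
  if (length(bad) == 0) TRUE else bad
}

#' Assess inter-protomer geometry of a dimer model
#'
#' Reports the minimum inter-protomer heavy-atom distance, the clash
#' count, the per-protomer interface residue sets (contacts at or below
#' the cutoff), and the Calpha-Calpha distances between corresponding
#' (and crossed) termini of the two protomers.
#'
#' @param model a `DimerModel`.
#' @param contact_cutoff heavy-atom contact distance, Angstrom.
#' @param clash_cutoff heavy-atom clash distance, Angstrom.
#' @return a `DimerAssessment`.
#' @export
assess_dimer <- function(model, contact_cutoff = 4.5, clash_cutoff = 2.2) {
  cont <- junction_continuity(model)
  if (!isTRUE(cont)) {
    stop("discontinuous junction: ", paste(cont, collapse = "; "))
  }
  s <- model$structure
  pa <- heavy_atoms(subset_structure(s, s$atoms$chain == "A"))
  pb <- heavy_atoms(subset_structure(s, s$atoms$chain == "B"))
  ma <- coords(pa); mb <- coords(pb)
  d2 <- outer(rowSums(ma^2), rowSums(mb^2), `+`) - 2 * ma %*% t(mb)
  d2[d2 < 0] <- 0
  min_d <- sqrt(min(d2))
  clash_count <- sum(d2 < clash_cutoff^2)
  contacts <- contact_pairs(pa, pb, contact_cutoff)
  iface_a <- sort(unique(contacts$resno_a))
  iface_b <- sort(unique(contacts$resno_b))

  term_atom <- function(p, which) {
    at <- p$atoms
    rn <- if (which == "N") min(at$resno) else max(at$resno)
    sub <- at[at$resno == rn, , drop = FALSE]
    ca <- sub[sub$name == "CA", , drop = FALSE]
    row <- if (nrow(ca) > 0) ca[1, ] else sub[1, ]
    as.numeric(row[c("x", "y", "z")])
  }
  nn <- vnorm(term_atom(pa, "N") - term_atom(pb, "N"))
  cc <- vnorm(term_atom(pa, "C") - term_atom(pb, "C"))
  nc <- vnorm(term_atom(pa, "N") - term_atom(pb, "C"))
  cn <- vnorm(term_atom(pa, "C") - term_atom(pb, "N"))

  structure(list(
    min_interprotein_distance = min_d,
    clash_count = clash_count,
    contacts = contacts,
    interface_residues = list(protomer_a = iface_a, protomer_b = iface_b),
    termini_distances = c(n_n = nn, c_c = cc, n_c = nc, c_n = cn),
    n_term_distance = nn, c_term_distance = cc,
    junction_geometry_ok = TRUE,
    contact_cutoff = contact_cutoff, clash_cutoff = clash_cutoff
  ), class = "DimerAssessment")
}

#' @export
print.DimerAssessment <- function(x, ...) {
  cat(sprintf(
    paste0("DimerAssessment: min inter-protomer %.2f A, %d clash(es), ",
           "%d+%d interface residues\n  termini N-N %.1f, C-C %.1f A\n"),
    x$min_interprotein_distance, x$clash_count,
    length(x$interface_residues$protomer_a),
    length(x$interface_residues$protomer_b),
    x$n_term_distance, x$c_term_distance))
  invisible(x)
}
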