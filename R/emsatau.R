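#' @title EMSA cooperativity: the tau factor and the two-site model
#'
#' @description The tau cooperativity statistic computed from gel-shift
#' band intensities, its background-normalized form, and the
#' two-identical-site equilibrium model that interprets it: with
#' per-site association k = 1/Kd and cooperativity factor omega,
#' \[PD\] = 2 k \[P\]\[D\] and \[P2D\] = omega k^2 \[P\]^2 \[D\].
#' Under this convention tau = 4\[P2D\]\[D\]/\[PD\]^2 equals omega exactly,
#' and independent sites give tau = 1.
#' @name emsatau
NULL

#' Two-identical-site equilibrium species
#'
#' Solves the protein mass balance by bracketed 1-D root finding for the
#' free protein concentration, then fills in all species. Mass balances
#' hold to 1e-9 relative.
#'
#' @param Kd_site per-site microscopic dissociation constant, nM.
#' @param omega cooperativity factor (1 = independent sites).
#' @param P_total total protein, nM.
#' @param D_total total probe, nM.
#' @return a `SpeciesState`: `P_free`, `D_free`, `PD`, `P2D` (nM).
#' @export
species_equilibrium <- function(Kd_site, omega, P_total, D_total) {
  stopifnot(Kd_site > 0, omega > 0, P_total >= 0, D_total >= 0)
  k <- 1 / Kd_site
  species_at <- function(P) {
    denom <- 1 + 2 * k * P + omega * k^2 * P^2
    D <- D_total / denom
    list(P_free = P, D_free = D, PD = 2 * k * P * D,
         P2D = omega * k^2 * P^2 * D)
  }
  if (P_total == 0) {
    out <- species_at(0)
  } else {
    f <- function(P) {
      s <- species_at(P)
      P + s$PD + 2 * s$P2D - P_total
    }
    # f(0) = -P_total < 0, f(P_total) >= 0: always bracketed
    root <- stats::uniroot(f, c(0, P_total), tol = 1e-12 * max(1, P_total))
    out <- species_at(root$root)
  }
  structure(out, class = "SpeciesState")
}

#' The tau cooperativity factor
#'
#' tau = 4 \[P2D\] \[D\] / \[PD\]^2; unit-free (any common signal unit
#' cancels). Undefined for non-positive monomer signal, returned as NA.
#'
#' @param D free-probe band signal.
#' @param PD monomer-complex band signal.
#' @param P2D dimer-complex band signal.
#' @return dimensionless tau, or NA when PD <= 0.
#' @export
tau <- function(D, PD, P2D) {
  ifelse(PD > 0, 4 * P2D * D / PD^2, NA_real_)
}

#' Background-normalized tau for one lane
#'
#' tau_normalized = 4 (\[P2D\]_lane - \[P2D\]_background) x \[D\]_lane /
#' (\[PD\]_lane - \[PD\]_background)^2. Lanes whose background-corrected
#' monomer signal is non-positive are undefined (NA), to be excluded
#' rather than clamped (clamping biases tau upward).
#'
#' @param lane named list/vector with `free`, `monomer`, `dimer` signals.
#' @param background same for the 0 nM protein lane.
#' @return dimensionless tau, or NA.
#' @export
tau_normalized <- function(lane, background) {
  pd <- lane[["monomer"]] - background[["monomer"]]
  p2d <- lane[["dimer"]] - background[["dimer"]]
  if (!is.finite(pd) || pd <= 0) return(NA_real_)
  4 * p2d * lane[["free"]] / pd^2
}

#' Per-lane tau analysis of an intensity table
#'
#' Applies the background-normalized tau to every protein lane of an
#' intensity table (the 0 nM lane is the background). Lanes with
#' non-positive corrected monomer signal are excluded with a reason.
#' Replicate tables can be pooled by concatenating their `per_lane` rows.
#'
#' @param table an `IntensityTable`.
#' @return a `TauResult`: per-lane tau, mean, sd, lanes used/excluded.
#' @export
analyze_titration <- function(table) {
  stopifnot(inherits(table, "IntensityTable"))
  bg_lane <- attr(table, "background_lane")
  bg <- table[table$lane == bg_lane, ]
  if (nrow(bg) != 1) stop("no background (0 nM protein) lane")
  lanes <- table[table$lane != bg_lane, , drop = FALSE]
  if (nrow(lanes) < 1) stop("no protein lanes to analyze")
  tv <- vapply(seq_len(nrow(lanes)), function(i) {
    tau_normalized(lanes[i, ], bg)
  }, numeric(1))
  per_lane <- data.frame(lane = lanes$lane, protein_nM = lanes$protein_nM,
                         tau = tv,
                         excluded = !is.finite(tv) | tv < 0)
  used <- per_lane$tau[!per_lane$excluded]
  structure(list(
    per_lane = per_lane,
    mean = if (length(used) > 0) mean(used) else NA_real_,
    sd = if (length(used) > 1) stats::sd(used) else NA_real_,
    lanes_used = sum(!per_lane$excluded),
    lanes_excluded = per_lane$lane[per_lane$excluded],
    background_lane = bg_lane
  ), class = "TauResult")
}

#' @export
print.TauResult <- function(x, ...) {
  cat(sprintf("TauResult: mean tau %.3g (sd %.3g) over %d lane(s)\n",
              x$mean, x$sd, x$lanes_used))
  if (length(x$lanes_excluded) > 0) {
    cat("  excluded lanes:", paste(x$lanes_excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pool tau results across replicate tables
#' @param ... `TauResult` objects.
#' @return pooled `TauResult`.
#' @export
pool_tau <- function(...) {
  results <- list(...)
  per_lane <- do.call(rbind, lapply(results, function(r) r$per_lane))
  used <- per_lane$tau[!per_lane$excluded]
  structure(list(
    per_lane = per_lane,
    mean = mean(used), sd = stats::sd(used),
    lanes_used = length(used),
    lanes_excluded = per_lane$lane[per_lane$excluded],
    background_lane = NA
  ), class = "TauResult")
}
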