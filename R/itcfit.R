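#' @title One-site ITC isotherm model and fitting
#'
#' @description Simulation and nonlinear least-squares fitting of one-site
#' binding isotherms for a perfusion-cell titration (macromolecule in the
#' cell, titrant in the syringe), with the standard dilution and
#' displaced-volume corrections, plus thermodynamic conversions. The
#' macromolecule here is the protein in the cell and the titrant the DNA
#' duplex in the syringe, so the stoichiometry n means DNA sites per
#' protein and is expected near 1.
#' @name itcfit
NULL

# Gas constant, kcal / (mol K)
R_KCAL <- 1.98720425e-3

#' Define a titration protocol
#'
#' @param cell_volume_ul working cell volume, microliter.
#' @param cell_uM macromolecule (cell) concentration, micromolar.
#' @param syringe_uM titrant (syringe) concentration, micromolar.
#' @param injection_volumes_ul per-injection volumes, microliter.
#' @param temperature_K temperature, Kelvin.
#' @return a `TitrationProtocol`.
#' @export
titration_protocol <- function(cell_volume_ul = 1400, cell_uM = 10,
                               syringe_uM = 100,
                               injection_volumes_ul = c(1, rep(14, 19)),
                               temperature_K = 293.15) {
  stopifnot(cell_volume_ul > 0, cell_uM > 0, syringe_uM > 0,
            temperature_K > 0, all(injection_volumes_ul > 0))
  structure(list(cell_volume_ul = cell_volume_ul, cell_uM = cell_uM,
                 syringe_uM = syringe_uM,
                 injection_volumes_ul = injection_volumes_ul,
                 temperature_K = temperature_K),
            class = "TitrationProtocol")
}

# Total concentrations in the cell after each injection with the
# perfusion-cell dilution convention (cumulative displaced volume).
titration_totals <- function(protocol) {
  V0 <- protocol$cell_volume_ul
  dv <- cumsum(protocol$injection_volumes_ul)
  f <- dv / V0
  M0 <- protocol$cell_uM * 1e-6
  X0 <- protocol$syringe_uM * 1e-6
  Mt <- M0 * (1 - f / 2) / (1 + f / 2)
  Xt <- X0 * f / (1 + f / 2)
  list(Mt = Mt, Xt = Xt, dv = protocol$injection_volumes_ul, V0 = V0)
}

# Cumulative bound heat (kcal) after injection i from the one-site
# binding quadratic.
cumulative_heats <- function(protocol, K, dH, n) {
  tt <- titration_totals(protocol)
  V0_l <- tt$V0 * 1e-6
  s <- 1 + tt$Xt / (n * tt$Mt) + 1 / (n * K * tt$Mt)
  disc <- s^2 - 4 * tt$Xt / (n * tt$Mt)
  disc[disc < 0] <- 0  # numerical guard at saturation
  n * tt$Mt * dH * V0_l / 2 * (s - sqrt(disc))
}

#' Simulate one-site injection heats
#'
#' Computes cumulative bound heat from the single-site quadratic (total
#' titrant, total macromolecule, association constant K, stoichiometry n),
#' with per-injection dilution of both species; the per-injection heat is
#' the difference of cumulative heats plus the displaced-volume term.
#'
#' @param protocol a `TitrationProtocol`.
#' @param K association constant, 1/M.
#' @param dH molar binding enthalpy, kcal/mol.
#' @param n stoichiometry (titrant sites per macromolecule).
#' @return an `Isotherm`: per-injection heat (microcal), normalized heat
#'   (kcal per mol injectant), molar ratio after each injection.
#' @export
one_site_heats <- function(protocol, K, dH, n = 1) {
  stopifnot(inherits(protocol, "TitrationProtocol"), K > 0, n > 0)
  Q <- cumulative_heats(protocol, K, dH, n)
  tt <- titration_totals(protocol)
  Qprev <- c(0, Q[-length(Q)])
  dQ <- Q - Qprev + (tt$dv / tt$V0) * (Q + Qprev) / 2
  heat_ucal <- dQ * 1e9
  isotherm_from_heats(protocol, heat_ucal)
}

#' Assemble an isotherm from measured injection heats
#' @param protocol a `TitrationProtocol`.
#' @param heat_ucal per-injection integrated heats, microcal.
#' @return an `Isotherm`.
#' @export
isotherm_from_heats <- function(protocol, heat_ucal) {
  if (length(heat_ucal) != length(protocol$injection_volumes_ul)) {
    stop("heat count does not match the injection schedule")
  }
  tt <- titration_totals(protocol)
  X0 <- protocol$syringe_uM * 1e-6
  mol_inj <- X0 * tt$dv * 1e-6  # mol of titrant per injection
  structure(list(
    protocol = protocol,
    heat_ucal = heat_ucal,
    ndh_kcal_per_mol = heat_ucal * 1e-9 / mol_inj,
    molar_ratio = tt$Xt / tt$Mt
  ), class = "Isotherm")
}

#' @export
print.Isotherm <- function(x, ...) {
  cat(sprintf("Isotherm: %d injections, molar ratio %.2f-%.2f\n",
              length(x$heat_ucal), min(x$molar_ratio), max(x$molar_ratio)))
  invisible(x)
}

#' Thermodynamic conversions from an association constant
#'
#' Standard relations with R = 1.98720425e-3 kcal/(mol K):
#' dG = -RT ln K, Kd(nM) = 1e9 / K, -TdS = dG - dH.
#'
#' @param K association constant, 1/M.
#' @param temperature_K temperature, Kelvin.
#' @param dH molar enthalpy, kcal/mol (optional, for -TdS).
#' @return list with `dG_kcal`, `Kd_nM` and (when dH given) `mTdS_kcal`.
#' @export
thermo_convert <- function(K, temperature_K = 293.15, dH = NULL) {
  stopifnot(K > 0, temperature_K > 0)
  dG <- -R_KCAL * temperature_K * log(K)
  out <- list(dG_kcal = dG, Kd_nM = 1e9 / K)
  if (!is.null(dH)) out$mTdS_kcal <- dG - dH
  out
}

#' Wiseman c parameter
#'
#' c = K * M * n with M the cell (macromolecule) concentration; fits are
#' considered reliable roughly for c in 1..1000.
#'
#' @param K association constant, 1/M.
#' @param M_uM cell concentration, micromolar.
#' @param n stoichiometry.
#' @return dimensionless c.
#' @export
wiseman_c <- function(K, M_uM, n = 1) K * M_uM * 1e-6 * n

#' Fit a one-site binding model to an isotherm
#'
#' Levenberg-Marquardt least squares on the normalized heats over
#' (log10 K, dH, n), with a deterministic multi-start over log-spaced K
#' when no start is given. The first injection (the small pre-injection)
#' is discarded by default. Derived quantities satisfy their defining
#' identities exactly.
#'
#' @param isotherm an `Isotherm`.
#' @param discard_first drop the first injection?
#' @param start optional list(K, dH, n) starting values.
#' @return a `OneSiteFit` with K (1/M), dH (kcal/mol), n, Kd_nM, dG_kcal,
#'   mTdS_kcal, c, residual norm and diagnostics.
#' @export
fit_one_site <- function(isotherm, discard_first = TRUE, start = NULL) {
  stopifnot(inherits(isotherm, "Isotherm"))
  protocol <- isotherm$protocol
  keep <- seq_along(isotherm$heat_ucal)
  if (discard_first) keep <- keep[-1]
  if (length(keep) < 5) stop("need at least 5 usable injections")
  y <- isotherm$ndh_kcal_per_mol[keep]
  if (all(abs(y) < 1e-12)) stop("degenerate data: all heats are zero")
  ratio <- isotherm$molar_ratio[keep]
  if (max(ratio) < 1) {
    warning("molar-ratio range does not span the transition; ",
            "fit may be unreliable")
  }
  model_ndh <- function(logK, dH, n) {
    iso <- one_site_heats(protocol, 10^logK, dH, n)
    iso$ndh_kcal_per_mol[keep]
  }
  dH0 <- y[which.max(abs(y))]
  starts <- if (!is.null(start)) {
    list(c(log10(start$K), start$dH, start$n))
  } else {
    lapply(c(5, 6, 7, 8, 9), function(lk) c(lk, dH0, 1))
  }
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = list(logK = s0[1], dH = s0[2], n = s0[3]),
        fn = function(par) y - model_ndh(par$logK, par$dH, par$n),
        lower = c(1, -1e4, 1e-3), upper = c(12, 1e4, 1e3),
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-14, ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) stop("one-site fit failed to converge from any start")
  p <- best$fit$par
  K <- 10^p$logK
  T <- protocol$temperature_K
  th <- thermo_convert(K, T, p$dH)
  cval <- wiseman_c(K, protocol$cell_uM, p$n)
  out <- structure(list(
    K = K, dH = p$dH, n = p$n,
    Kd_nM = th$Kd_nM, dG_kcal = th$dG_kcal, mTdS_kcal = th$mTdS_kcal,
    c = cval,
    c_reliable = cval >= 1 && cval <= 1000,
    residual_norm = best$rn,
    deviance = best$fit$deviance,
    n_injections_used = length(keep),
    covariance = tryCatch(solve(best$fit$hessian), error = function(e) NULL)
  ), class = "OneSiteFit")
  if (!out$c_reliable) {
    warning(sprintf("Wiseman c = %.3g outside [1, 1000]; fitted K unreliable",
                    cval))
  }
  out
}

#' @export
print.OneSiteFit <- function(x, ...) {
  cat(sprintf(
    paste0("OneSiteFit: K %.3g /M (Kd %.1f nM), dH %.2f kcal/mol, n %.3f\n",
           "  dG %.2f, -TdS %.2f kcal/mol, c %.0f\n"),
    x$K, x$Kd_nM, x$dH, x$n, x$dG_kcal, x$mTdS_kcal, x$c))
  invisible(x)
}
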