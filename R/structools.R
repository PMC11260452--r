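#' @title Structure comparison and interface analysis
#'
#' @description Least-squares superposition (proper rotations only),
#' Shrake-Rupley solvent-accessible surface area on a deterministic
#' sphere-point set, buried interface area from three SASA evaluations,
#' and residue-residue contact detection.
#' @name structools
NULL

# Bundled van der Waals radii (Angstrom) for SASA.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
               MG = 1.73, NA. = 2.27, K = 2.75, CL = 1.75, ZN = 1.39,
               RB = 3.03, X = 1.70)

atom_radii <- function(structure, radii_set = "standard", default_radius = NULL) {
  if (radii_set != "standard") stop("unknown radii set: ", radii_set)
  el <- toupper(structure$atoms$element)
  el[el == "NA"] <- "NA."
  r <- VDW_RADII[el]
  if (anyNA(r)) {
    missing <- unique(structure$atoms$element[is.na(r)])
    if (is.null(default_radius)) {
      stop("no van der Waals radius for element(s): ",
           paste(missing, collapse = ", "),
           "; supply default_radius to override")
    }
    r[is.na(r)] <- default_radius
  }
  unname(r)
}

# Matched coordinate pairs between two structures.
# selection = "name-match": atoms matched by (chain, resno, atom name),
# with an optional chain equivalence map for the mobile structure;
# "sequential": row-by-row (requires equal atom counts).
match_atoms <- function(mobile, reference, selection = "name-match",
                        chain_map = NULL, strict = FALSE) {
  if (identical(selection, "sequential")) {
    if (nrow(mobile$atoms) != nrow(reference$atoms)) {
      stop("sequential matching requires equal atom counts")
    }
    return(list(mobile = coords(mobile), reference = coords(reference),
                n = nrow(mobile$atoms),
                description = "sequential (all atoms, row order)"))
  }
  ma <- mobile$atoms
  ra <- reference$atoms
  mchain <- ma$chain
  if (!is.null(chain_map)) {
    mapped <- chain_map[mchain]
    mchain <- ifelse(is.na(mapped), mchain, mapped)
  }
  mkey <- paste(mchain, ma$resno, ma$name, sep = "|")
  rkey <- paste(ra$chain, ra$resno, ra$name, sep = "|")
  idx <- match(mkey, rkey)
  matched <- which(!is.na(idx))
  if (strict && length(matched) < nrow(ma)) {
    miss <- utils::head(mkey[is.na(idx)], 10)
    stop("strict matching failed for ", sum(is.na(idx)), " atom(s), e.g.: ",
         paste(miss, collapse = "; "))
  }
  list(mobile = coords(mobile)[matched, , drop = FALSE],
       reference = coords(reference)[idx[matched], , drop = FALSE],
       n = length(matched),
       description = sprintf("name-match on (chain, resno, atom): %d pairs",
                             length(matched)))
}

#' Optimal rigid superposition of two structures
#'
#' Least-squares proper-rotation (Kabsch) superposition of matched atoms;
#' the RMSD is computed after applying the transform.
#'
#' @param mobile,reference `Structure` objects.
#' @param selection `"name-match"` (by chain/residue/atom identity,
#'   optionally through `chain_map`) or `"sequential"`.
#' @param chain_map named character vector mapping mobile chain ids to
#'   reference chain ids (chain-equivalence map for comparing copies).
#' @param include_waters include solvent in the matched set?
#' @param strict error if any mobile atom fails to match?
#' @return a `SuperpositionResult`: rotation (det +1), translation, rmsd,
#'   n_atoms, atom_selection description.
#' @export
superpose <- function(mobile, reference, selection = "name-match",
                      chain_map = NULL, include_waters = FALSE,
                      strict = FALSE) {
  mobile <- strip_waters(mobile, include_waters)
  reference <- strip_waters(reference, include_waters)
  m <- match_atoms(mobile, reference, selection, chain_map, strict)
  if (m$n < 3) stop("selection yields fewer than 3 matched atom pairs")
  fit <- kabsch(m$mobile, m$reference)
  structure(list(
    rotation = fit$rotation, translation = fit$translation,
    rmsd = fit$rmsd, n_atoms = m$n, atom_selection = m$description
  ), class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("SuperpositionResult: rmsd %.4f A over %d atoms (%s)\n",
              x$rmsd, x$n_atoms, x$atom_selection))
  invisible(x)
}

#' Apply a rigid transform to a structure
#' @param structure a `Structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector.
#' @return transformed `Structure`.
#' @export
transform_structure <- function(structure, rotation, translation) {
  xyz <- apply_rigid(coords(structure), rotation, translation)
  out <- structure
  out$atoms$x <- xyz[, 1]; out$atoms$y <- xyz[, 2]; out$atoms$z <- xyz[, 3]
  out
}

# Deterministic, nearly uniform unit-sphere point set (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerically integrated accessible area per atom on an evenly
#' distributed deterministic sphere-point set. Waters are excluded by
#' default (explicit flag to include).
#'
#' @param structure a `Structure`.
#' @param probe_radius probe radius, Angstrom (water = 1.4).
#' @param n_sphere_points quadrature points per atom.
#' @param radii_set named radii table (`"standard"` bundled).
#' @param default_radius fallback radius for unknown elements (errors
#'   without it).
#' @param include_waters include solvent atoms?
#' @return a `SasaResult`: `per_atom_area`, `total`, plus the settings.
#' @export
sasa <- function(structure, probe_radius = 1.4, n_sphere_points = 960,
                 radii_set = "standard", default_radius = NULL,
                 include_waters = FALSE) {
  structure <- strip_waters(structure, include_waters)
  xyz <- coords(structure)
  r <- atom_radii(structure, radii_set, default_radius) + probe_radius
  n <- nrow(xyz)
  pts <- sphere_points(n_sphere_points)
  per_atom <- numeric(n)
  # neighbor lists via cell-free cutoff on squared distances
  maxr <- max(r)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r[i] + maxr)^2 & d2 > 1e-12)
    nb <- nb[sqrt(d2[nb]) < r[i] + r[nb]]
    surf <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    if (length(nb) > 0) {
      acc <- rep(TRUE, n_sphere_points)
      for (j in nb) {
        dd <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
          (surf[, 3] - xyz[j, 3])^2
        acc <- acc & (dd >= r[j]^2)
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    per_atom[i] <- frac * 4 * pi * r[i]^2
  }
  structure(list(per_atom_area = per_atom, total = sum(per_atom),
                 probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points, radii_set = radii_set),
            class = "SasaResult")
}

#' @export
print.SasaResult <- function(x, ...) {
  cat(sprintf("SasaResult: total %.1f A^2 (%d atoms, %d points, probe %.2f)\n",
              x$total, length(x$per_atom_area), x$n_sphere_points,
              x$probe_radius))
  invisible(x)
}

combine_structures <- function(a, b) {
  aa <- a$atoms; ba <- b$atoms
  shared <- intersect(paste(aa$chain, aa$resno, aa$name),
                      paste(ba$chain, ba$resno, ba$name))
  if (length(shared) > 0) stop("components share atoms; cannot combine")
  ba$serial <- ba$serial + max(aa$serial)
  new_structure(rbind(aa, ba), metadata = list(combined = TRUE))
}

#' Interface analysis between two components
#'
#' Buried areas are computed from three SASA evaluations (A alone, B
#' alone, A+B). The headline `buried_area_half` is half the total change,
#' (SASA_A + SASA_B - SASA_AB)/2 (the per-side "buries X A^2" convention);
#' the per-component losses are also reported so the alternative
#' convention is explicit. Contacts are residue pairs with any heavy-atom
#' distance at or below `cutoff`.
#'
#' @param component_a,component_b disjoint `Structure` objects.
#' @param cutoff heavy-atom contact distance, Angstrom.
#' @param ... passed to [sasa()].
#' @return an `InterfaceReport`.
#' @export
interface_report <- function(component_a, component_b, cutoff = 4.5, ...) {
  if (nrow(component_a$atoms) == 0 || nrow(component_b$atoms) == 0) {
    stop("empty component")
  }
  sa <- sasa(component_a, ...)
  sb <- sasa(component_b, ...)
  sab <- sasa(combine_structures(component_a, component_b), ...)
  na <- nrow(strip_waters(component_a)$atoms)
  per_a <- sa$total - sum(sab$per_atom_area[seq_len(na)])
  per_b <- sb$total - sum(sab$per_atom_area[-seq_len(na)])
  contacts <- contact_pairs(component_a, component_b, cutoff)
  structure(list(
    buried_area_half = (sa$total + sb$total - sab$total) / 2,
    buried_area_per_component = c(a = per_a, b = per_b),
    contact_pairs = contacts, cutoff = cutoff
  ), class = "InterfaceReport")
}

#' @export
print.InterfaceReport <- function(x, ...) {
  cat(sprintf(
    "InterfaceReport: buried %.1f A^2 (half-dSASA), %d residue contacts <= %.1f A\n",
    x$buried_area_half, nrow(x$contact_pairs), x$cutoff))
  invisible(x)
}

heavy_atoms <- function(structure) {
  subset_structure(structure, toupper(structure$atoms$element) != "H")
}

#' Residue-residue contacts between two components
#'
#' @param component_a,component_b `Structure` objects.
#' @param cutoff heavy-atom distance cutoff, Angstrom.
#' @return data.frame: residue identifiers on both sides and the minimum
#'   heavy-atom distance per residue pair (<= cutoff).
#' @export
contact_pairs <- function(component_a, component_b, cutoff = 4.5) {
  a <- heavy_atoms(component_a)$atoms
  b <- heavy_atoms(component_b)$atoms
  am <- as.matrix(a[, c("x", "y", "z")])
  bm <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(am^2), rowSums(bm^2), `+`) - 2 * am %*% t(bm)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(data.frame(chain_a = character(0), resno_a = integer(0),
                      resname_a = character(0), chain_b = character(0),
                      resno_b = integer(0), resname_b = character(0),
                      min_distance = numeric(0)))
  }
  df <- data.frame(
    chain_a = a$chain[hit[, 1]], resno_a = a$resno[hit[, 1]],
    resname_a = a$resname[hit[, 1]],
    chain_b = b$chain[hit[, 2]], resno_b = b$resno[hit[, 2]],
    resname_b = b$resname[hit[, 2]],
    d = sqrt(d2[hit])
  )
  key <- paste(df$chain_a, df$resno_a, df$chain_b, df$resno_b)
  agg <- tapply(df$d, key, min)
  first <- df[!duplicated(key), , drop = FALSE]
  first <- first[order(match(paste(first$chain_a, first$resno_a,
                                   first$chain_b, first$resno_b),
                             names(agg))), ]
  first$min_distance <- as.numeric(agg[paste(first$chain_a, first$resno_a,
                                             first$chain_b, first$resno_b)])
  first$d <- NULL
  rownames(first) <- NULL
  first[order(first$chain_a, first$resno_a, first$resno_b), ]
}
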