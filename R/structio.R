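#' @title Structural and tabular input/output
#'
#' @description Readers and writers for the formats the pipeline touches
#' (PDB/mmCIF structures, FASTA/FASTQ reads, MEME-minimal and HOMER motif
#' text, TSV intensity and titration tables) plus the shared record types.
#' Coordinates are in Angstrom throughout; residue numbering follows the
#' source file; internal indices are 1-based (R convention).
#' @name structio
NULL

NUCLEIC_RESNAMES <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "T", "U")
WATER_RESNAMES <- c("HOH", "WAT", "H2O", "DOD")

base_letter <- function(resname) {
  x <- sub("^D", "", resname)
  ifelse(x %in% c("A", "C", "G", "T", "U"), x, NA_character_)
}

complement_base <- function(b) c(A = "T", T = "A", G = "C", C = "G", U = "A")[b]

#' Construct a Structure object
#'
#' A `Structure` is an ordered atom table plus free-text metadata. Atom
#' serials must be unique and coordinates finite.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`,
#'   `chain`, `resno`, `x`, `y`, `z`, `element`, `occ`, `b`.
#' @param metadata named list (title, accession, provenance notes).
#' @return an object of class `Structure`.
#' @export
new_structure <- function(atoms, metadata = list()) {
  required <- c("serial", "name", "resname", "chain", "resno",
                "x", "y", "z", "element", "occ", "b")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    stop("atom table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("empty structure")
  if (anyDuplicated(atoms$serial)) stop("atom serials are not unique")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  if (any(!nzchar(atoms$element))) stop("empty element symbols")
  if (any(atoms$occ < 0 | atoms$occ > 1)) stop("occupancy outside [0, 1]")
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)),
                       atoms$resno, atoms$serial), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, metadata = metadata), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  ch <- table(x$atoms$chain)
  cat("Structure:", nrow(x$atoms), "atoms,",
      length(ch), "chain(s):",
      paste(sprintf("%s (%d)", names(ch), ch), collapse = ", "), "\n")
  invisible(x)
}

coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

structure_chains <- function(structure) unique(structure$atoms$chain)

subset_structure <- function(structure, keep) {
  atoms <- structure$atoms[keep, , drop = FALSE]
  if (nrow(atoms) == 0) stop("selection removed every atom")
  new_structure(atoms, structure$metadata)
}

#' Keep or drop solvent/ion records
#'
#' Waters and ions are retained on read but excluded by default from
#' geometry selections; this helper makes the selection explicit.
#' @param structure a `Structure`.
#' @param include_waters keep water records?
#' @return filtered `Structure`.
#' @export
strip_waters <- function(structure, include_waters = FALSE) {
  if (include_waters) return(structure)
  subset_structure(structure, !(structure$atoms$resname %in% WATER_RESNAMES))
}

is_nucleic_chain <- function(structure, chain) {
  res <- unique(structure$atoms$resname[structure$atoms$chain == chain])
  res <- setdiff(res, WATER_RESNAMES)
  length(res) > 0 && all(res %in% NUCLEIC_RESNAMES)
}

#' Read a macromolecular structure
#'
#' Parses PDB or mmCIF through bio3d, keeps all ATOM/HETATM records in file
#' order and resolves alternate locations to the highest-occupancy copy
#' (ties broken by altloc letter order).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return a `Structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e))
  )
  a <- parsed$atom
  if (is.null(a) || nrow(a) == 0) stop("empty structure: ", path)
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    resname = trimws(a$resid),
    chain = ifelse(is.na(a$chain) | a$chain == "", " ", a$chain),
    resno = as.integer(a$resno),
    x = a$x, y = a$y, z = a$z,
    element = trimws(ifelse(is.na(a$elesy) | a$elesy == "",
                            substr(trimws(a$elety), 1, 1), a$elesy)),
    occ = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    alt = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
    stringsAsFactors = FALSE
  )
  # alternate locations: keep highest occupancy, tie -> first altloc letter
  key <- paste(atoms$chain, atoms$resno, atoms$name, sep = "|")
  if (any(nzchar(atoms$alt))) {
    ord <- order(key, -atoms$occ, atoms$alt)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$name,
                                     sep = "|")), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  atoms$alt <- NULL
  new_structure(atoms, metadata = list(source = path, format = format))
}

#' Write a structure as PDB
#'
#' @param structure a `Structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(a)),
    resno = a$resno, resid = a$resname, chain = a$chain,
    eleno = a$serial, elety = a$name, o = a$occ, b = a$b, elesy = a$element
  )
  invisible(path)
}

base_ring_atom_names <- function(base) {
  if (base %in% c("A", "G")) c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  else c("N1", "C2", "N3", "C4", "C5", "C6")
}

residue_atom_xyz <- function(structure, chain, resno, names) {
  a <- structure$atoms
  sel <- a$chain == chain & a$resno == resno & a$name %in% names
  sub <- a[sel, , drop = FALSE]
  sub <- sub[match(names, sub$name), , drop = FALSE]
  if (anyNA(sub$name)) return(NULL)
  as.matrix(sub[, c("x", "y", "z")])
}

base_plane_normal <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  unit(svd(c0)$v[, 3])
}

#' Extract a paired duplex from two nucleic chains
#'
#' Watson-Crick pairs are identified by base complementarity plus a
#' geometric criterion: glycosidic-face N1-N3 distance <= 3.5 Angstrom and
#' base-plane angle <= 65 degrees. Unpaired terminal residues are reported
#' as overhangs.
#'
#' @param structure a `Structure`.
#' @param chain_pair character vector of two chain ids; first is the sense
#'   strand.
#' @return a `DuplexStructure`: the nucleic atoms, both 5'->3' sequences,
#'   the pairing map and per-strand overhangs.
#' @export
extract_duplex <- function(structure, chain_pair) {
  stopifnot(length(chain_pair) == 2)
  for (ch in chain_pair) {
    if (!is_nucleic_chain(structure, ch)) {
      stop("chain ", ch, " is not a nucleic-acid chain")
    }
  }
  a <- structure$atoms
  res1 <- unique(a$resno[a$chain == chain_pair[1]])
  res2 <- unique(a$resno[a$chain == chain_pair[2]])
  res1 <- sort(res1); res2 <- sort(res2)
  base_of <- function(chain, resno) {
    base_letter(a$resname[a$chain == chain & a$resno == resno][1])
  }
  b1 <- vapply(res1, function(r) base_of(chain_pair[1], r), character(1))
  b2 <- vapply(res2, function(r) base_of(chain_pair[2], r), character(1))

  # pairing atom: N1 for purines, N3 for pyrimidines
  wc_atom <- function(base) if (base %in% c("A", "G")) "N1" else "N3"
  pt1 <- lapply(seq_along(res1), function(i)
    residue_atom_xyz(structure, chain_pair[1], res1[i], wc_atom(b1[i])))
  pt2 <- lapply(seq_along(res2), function(i)
    residue_atom_xyz(structure, chain_pair[2], res2[i], wc_atom(b2[i])))
  nrm1 <- lapply(seq_along(res1), function(i) {
    xyz <- residue_atom_xyz(structure, chain_pair[1], res1[i],
                            base_ring_atom_names(b1[i]))
    if (is.null(xyz)) NULL else base_plane_normal(xyz)
  })
  nrm2 <- lapply(seq_along(res2), function(i) {
    xyz <- residue_atom_xyz(structure, chain_pair[2], res2[i],
                            base_ring_atom_names(b2[i]))
    if (is.null(xyz)) NULL else base_plane_normal(xyz)
  })

  pairs <- NULL
  for (i in seq_along(res1)) {
    if (is.na(b1[i]) || is.null(pt1[[i]]) || is.null(nrm1[[i]])) next
    best_j <- NA_integer_; best_d <- Inf
    for (j in seq_along(res2)) {
      if (is.na(b2[j]) || is.null(pt2[[j]]) || is.null(nrm2[[j]])) next
      if (complement_base(b1[i]) != b2[j]) next
      d <- vnorm(pt1[[i]] - pt2[[j]])
      if (d > 3.5) next
      ang <- angle_between_deg(nrm1[[i]], nrm2[[j]])
      ang <- min(ang, 180 - ang)  # normals are orientation-free
      if (ang > 65) next
      if (d < best_d) { best_d <- d; best_j <- j }
    }
    if (!is.na(best_j)) {
      pairs <- rbind(pairs, data.frame(sense_idx = i, anti_idx = best_j,
                                       dist = best_d))
    }
  }
  if (is.null(pairs) || nrow(pairs) == 0) {
    stop("no Watson-Crick pairs found between chains ",
         chain_pair[1], " and ", chain_pair[2])
  }
  # antiparallel duplex: anti index strictly decreasing along the sense strand
  pairs <- pairs[order(pairs$sense_idx), , drop = FALSE]
  keep <- rep(TRUE, nrow(pairs))
  last <- Inf
  for (r in seq_len(nrow(pairs))) {
    if (pairs$anti_idx[r] >= last) keep[r] <- FALSE else last <- pairs$anti_idx[r]
  }
  pairs <- pairs[keep, , drop = FALSE]

  keep_atoms <- a$chain %in% chain_pair
  dup_struct <- subset_structure(structure, keep_atoms)
  overhang1 <- setdiff(seq_along(res1), pairs$sense_idx)
  overhang2 <- setdiff(seq_along(res2), pairs$anti_idx)
  structure(list(
    structure = dup_struct,
    sense_chain = chain_pair[1],
    anti_chain = chain_pair[2],
    sense_resno = res1,
    anti_resno = res2,
    sense_sequence = paste(ifelse(is.na(b1), "N", b1), collapse = ""),
    antisense_sequence = paste(ifelse(is.na(b2), "N", b2), collapse = ""),
    pairing = pairs[, c("sense_idx", "anti_idx")],
    overhangs = list(sense = overhang1, antisense = overhang2)
  ), class = "DuplexStructure")
}

#' @export
print.DuplexStructure <- function(x, ...) {
  cat("DuplexStructure:", nrow(x$pairing), "base pairs;",
      "sense", x$sense_sequence, "\n")
  invisible(x)
}

#' Construct a position weight matrix object
#'
#' @param mat numeric matrix, positions x 4, columns A, C, G, T; each row
#'   is renormalized to sum 1.
#' @param background base frequencies (default uniform).
#' @param pseudocount probability floor applied before log-odds scoring.
#' @param name motif name.
#' @return object of class `MotifMatrix`.
#' @export
motif_matrix <- function(mat, background = rep(0.25, 4),
                         pseudocount = 0.001, name = "motif") {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4) stop("motif matrix must have 4 columns (A, C, G, T)")
  if (any(mat < 0)) stop("negative motif weight")
  rs <- rowSums(mat)
  if (any(rs <= 0)) stop("motif row with zero total weight")
  if (any(abs(rs - 1) > 1e-6)) {
    warning("motif rows renormalized to sum 1")
  }
  mat <- mat / rs
  colnames(mat) <- c("A", "C", "G", "T")
  rownames(mat) <- NULL
  background <- background / sum(background)
  structure(list(mat = mat, background = background,
                 pseudocount = pseudocount, name = name),
            class = "MotifMatrix")
}

#' @export
print.MotifMatrix <- function(x, ...) {
  cons <- paste(colnames(x$mat)[apply(x$mat, 1, which.max)], collapse = "")
  cat("MotifMatrix '", x$name, "': ", nrow(x$mat), " positions, consensus ",
      cons, "\n", sep = "")
  invisible(x)
}

motif_length <- function(pwm) nrow(pwm$mat)

#' Read a motif matrix
#'
#' Supports MEME minimal text and HOMER `.motif` formats. Probabilities are
#' renormalized to sum 1 per position (with a warning when the input rows
#' do not).
#'
#' @param path file path.
#' @param format `"auto"`, `"meme_minimal"` or `"homer"`.
#' @return a `MotifMatrix`.
#' @export
read_motif <- function(path, format = c("auto", "meme_minimal", "homer")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^MEME version", lines))) "meme_minimal"
    else if (any(grepl("^>", lines))) "homer"
    else stop("cannot determine motif format of ", path)
  }
  if (format == "meme_minimal") {
    mi <- grep("^MOTIF", lines)
    if (length(mi) == 0) stop("no MOTIF block in ", path)
    name <- trimws(sub("^MOTIF\\s+", "", lines[mi[1]]))
    li <- grep("^letter-probability matrix", lines)
    if (length(li) == 0) stop("no letter-probability matrix in ", path)
    rows <- character(0)
    k <- li[1] + 1
    while (k <= length(lines) && grepl("^\\s*[0-9eE.+-]", lines[k])) {
      rows <- c(rows, lines[k]); k <- k + 1
    }
    bgl <- grep("^Background letter frequencies", lines)
    background <- rep(0.25, 4)
    if (length(bgl) > 0 && bgl[1] + 1 <= length(lines)) {
      toks <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(toks))
      vals <- vals[!is.na(vals)]
      if (length(vals) == 4) background <- vals
    }
  } else {
    hi <- grep("^>", lines)
    if (length(hi) == 0) stop("no HOMER header line in ", path)
    toks <- strsplit(sub("^>", "", lines[hi[1]]), "\t")[[1]]
    name <- if (length(toks) >= 2) toks[2] else toks[1]
    rows <- lines[(hi[1] + 1):length(lines)]
    rows <- rows[grepl("^\\s*[0-9eE.+-]", rows)]
    background <- rep(0.25, 4)
  }
  if (length(rows) == 0) stop("motif matrix has no rows in ", path)
  mat <- do.call(rbind, lapply(rows, function(r) {
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])
  }))
  if (ncol(mat) != 4) stop("motif rows must have 4 columns in ", path)
  motif_matrix(mat, background = background, name = name)
}

#' Write a motif matrix in MEME minimal format
#'
#' @param pwm a `MotifMatrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_motif <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f",
            pwm$background[1], pwm$background[2],
            pwm$background[3], pwm$background[4]), "",
    paste("MOTIF", pwm$name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
            nrow(pwm$mat))
  ), con)
  apply(pwm$mat, 1, function(r) {
    writeLines(sprintf(" %8.6f %8.6f %8.6f %8.6f", r[1], r[2], r[3], r[4]), con)
  })
  invisible(path)
}

#' Read sequence records from FASTA or FASTQ
#'
#' @param path file path.
#' @return data.frame with columns `id` and `sequence` (IUPAC DNA letters).
#'   An empty file yields an empty data.frame, not an error.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fastq <- grepl("\\.(fastq|fq)$", path, ignore.case = TRUE)
  if (file.size(path) == 0) {
    return(data.frame(id = character(0), sequence = character(0)))
  }
  set <- Biostrings::readDNAStringSet(path, format = if (fastq) "fastq" else "fasta")
  data.frame(id = names(set), sequence = as.character(set),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequence records as FASTA
#'
#' @param records data.frame with `id` and `sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads <- function(records, path) {
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an EMSA band-intensity table
#'
#' Expects a TSV with header columns `lane`, `protein_nM`, `free`,
#' `monomer`, `dimer` and optionally `probe_nM`. Exactly one lane must have
#' 0 nM protein; it is flagged as the background lane.
#'
#' @param path TSV file.
#' @param probe_nM probe concentration if not carried as a column.
#' @return an `IntensityTable` data.frame with attributes `probe_nM` and
#'   `background_lane`.
#' @export
read_intensity_table <- function(path, probe_nM = 35) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("lane", "protein_nM", "free", "monomer", "dimer")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("intensity table missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- which(tab$free < 0 | tab$monomer < 0 | tab$dimer < 0)
  if (length(bad) > 0) {
    stop("negative band signal on row(s): ", paste(bad, collapse = ", "))
  }
  if (any(tab$protein_nM < 0)) stop("negative protein concentration")
  if ("probe_nM" %in% names(tab)) probe_nM <- tab$probe_nM[1]
  if (probe_nM < 0) stop("negative probe concentration")
  as_intensity_table(tab[, required], probe_nM = probe_nM)
}

#' Assemble an intensity table from lane data
#'
#' @param tab data.frame with `lane`, `protein_nM`, `free`, `monomer`, `dimer`.
#' @param probe_nM probe concentration (nM).
#' @return an `IntensityTable`.
#' @export
as_intensity_table <- function(tab, probe_nM = 35) {
  bg <- which(tab$protein_nM == 0)
  if (length(bg) != 1) {
    stop("expected exactly one background (0 nM protein) lane, found ",
         length(bg))
  }
  attr(tab, "probe_nM") <- probe_nM
  attr(tab, "background_lane") <- tab$lane[bg]
  class(tab) <- c("IntensityTable", "data.frame")
  tab
}

#' Write an intensity table as TSV
#' @param tab an `IntensityTable`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(tab, path) {
  out <- as.data.frame(tab)
  out$probe_nM <- attr(tab, "probe_nM")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ITC titration table
#'
#' TSV with columns `injection`, `volume_ul`, `heat_ucal`; the protocol
#' (cell volume, concentrations, temperature) rides in `# key value`
#' comment lines or is supplied via `protocol`.
#'
#' @param path TSV file.
#' @param protocol optional `titration_protocol` overriding the header.
#' @return an `Isotherm` (see [one_site_heats()]).
#' @export
read_titration <- function(path, protocol = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    toks <- strsplit(trimws(sub("^#\\s*", "", h)), "\\s+")[[1]]
    if (length(toks) == 2) kv[[toks[1]]] <- as.numeric(toks[2])
  }
  tab <- utils::read.delim(textConnection(lines[!grepl("^#", lines)]),
                           stringsAsFactors = FALSE)
  required <- c("injection", "volume_ul", "heat_ucal")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("titration table missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.null(protocol)) {
    need <- c("cell_volume_ul", "cell_uM", "syringe_uM", "temperature_K")
    if (!all(need %in% names(kv))) {
      stop("titration header must carry ", paste(need, collapse = ", "),
           " or a protocol must be supplied")
    }
    protocol <- titration_protocol(
      cell_volume_ul = kv$cell_volume_ul, cell_uM = kv$cell_uM,
      syringe_uM = kv$syringe_uM,
      injection_volumes_ul = tab$volume_ul,
      temperature_K = kv$temperature_K
    )
  }
  if (any(tab$volume_ul <= 0)) stop("non-positive injection volume")
  isotherm_from_heats(protocol, tab$heat_ucal)
}

#' Write an isotherm as TSV
#' @param iso an `Isotherm`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_titration <- function(iso, path) {
  p <- iso$protocol
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s %.10g",
                     c("cell_volume_ul", "cell_uM", "syringe_uM", "temperature_K"),
                     c(p$cell_volume_ul, p$cell_uM, p$syringe_uM, p$temperature_K)),
             con)
  utils::write.table(
    data.frame(injection = seq_along(p$injection_volumes_ul),
               volume_ul = p$injection_volumes_ul,
               heat_ucal = iso$heat_ucal),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
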