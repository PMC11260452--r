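# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

# Minimal hand-written PDB text with three atoms.
three_atom_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       3.200   3.300   3.000  1.00 10.00           C",
    "END")
  writeLines(lines, path)
  path
}

# PDB with alternate locations: altloc A occ 0.4, altloc B occ 0.6 for CA;
# altloc A/B at occ 0.5 each for CB (tie -> altloc letter order).
altloc_pdb <- function(path) {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CB AALA A   1       1.000   1.000   0.000  0.50 10.00           C",
    "ATOM      4  CB BALA A   1       5.000   5.000   0.000  0.50 10.00           C",
    "END")
  writeLines(lines, path)
  path
}

# The crystallized 15-mer strands: a 14-bp core with one 5' overhang per
# strand, derived from the printed sequences by building the padded
# 16-mer and deleting the residues that pair with each overhang.
crystal_duplex_structure <- function() {
  padded <- build_duplex("TGAGCTAATTAAAGCT")
  a <- padded$structure$atoms
  keep <- !(a$chain == "A" & a$resno == 16) & !(a$chain == "B" & a$resno == 16)
  subset_structure(padded$structure, keep)
}

# A duplex with one kinked step (roll/tilt at a single interior step) and
# ideal-B steps elsewhere.
kinked_duplex <- function(n = 15, at = 7, roll = 20, tilt = 0) {
  steps <- data.frame(shift = 0, slide = 0, rise = 3.38, tilt = 0, roll = 0,
                      twist = 36)[rep(1, n - 1), ]
  steps$roll[at] <- roll
  steps$tilt[at] <- tilt
  build_duplex(strrep("A", n), steps = steps)
}

random_steps <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    shift = runif(n, -1, 1), slide = runif(n, -1, 1),
    rise = runif(n, 3.0, 3.7), tilt = runif(n, -8, 8),
    roll = runif(n, -8, 8), twist = runif(n, 25, 40)))
}

random_rotation <- function(seed = 1) {
  withr::with_seed(seed, {
    ax <- rnorm(3)
    th <- runif(1, 0, pi)
    u <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  })
}

rigid_move <- function(structure, R, t) {
  hdcoop::transform_structure(structure, R, t)
}

# A tiny intensity table mirroring the five-lane titration layout
# (0/50/100/200/400 nM protein).
five_lane_tsv <- function(path) {
  tab <- data.frame(
    lane = 1:5, protein_nM = c(0, 50, 100, 200, 400),
    free = c(3500, 2400, 1500, 700, 200),
    monomer = c(20, 400, 500, 450, 300),
    dimer = c(15, 500, 1500, 2400, 3100),
    probe_nM = 35)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

meme_minimal_text <- function(path, rows,
                              name = "test_motif",
                              background = rep(0.25, 4)) {
  writeLines(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "Background letter frequencies",
    sprintf("A %.3f C %.3f G %.3f T %.3f", background[1], background[2],
            background[3], background[4]), "",
    paste("MOTIF", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
            nrow(rows)),
    apply(rows, 1, function(r) sprintf(" %g %g %g %g", r[1], r[2], r[3], r[4]))
  ), path)
  path
}
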