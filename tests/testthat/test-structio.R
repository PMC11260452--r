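test_that("a hand-written PDB is read verbatim and round-trips", {
  path <- withr::local_tempfile(fileext = ".pdb")
  three_atom_pdb(path)
  s <- read_structure(path)
  expect_s3_class(s, "Structure")
  expect_equal(nrow(s$atoms), 3)
  expect_equal(s$atoms$x, c(1.0, 2.5, 3.2))
  expect_equal(s$atoms$name, c("N", "CA", "C"))

  out <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, out)
  s2 <- read_structure(out)
  expect_equal(s2$atoms$x, s$atoms$x, tolerance = 1e-3)
  expect_equal(s2$atoms$resname, s$atoms$resname)
  expect_equal(s2$atoms$chain, s$atoms$chain)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
})

test_that("alternate locations resolve to highest occupancy, ties by letter", {
  path <- withr::local_tempfile(fileext = ".pdb")
  altloc_pdb(path)
  s <- read_structure(path)
  expect_equal(nrow(s$atoms), 2)
  # CA: occ 0.6 copy at x = 9 wins; CB: tie -> altloc A at x = 1
  expect_equal(s$atoms$x[s$atoms$name == "CA"], 9)
  expect_equal(s$atoms$x[s$atoms$name == "CB"], 1)
})

test_that("reading a missing or empty structure errors", {
  expect_error(read_structure("no-such-file.pdb"), "not found")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", path)
  expect_error(read_structure(path))
})

test_that("extract_duplex recovers the builder's pairing exactly", {
  d <- build_duplex("ATGCATGCAT")
  e <- extract_duplex(d$structure, c("A", "B"))
  expect_equal(nrow(e$pairing), 10)
  expect_equal(e$pairing$anti_idx, rev(seq_len(10)))
  expect_length(e$overhangs$sense, 0)
  expect_length(e$overhangs$antisense, 0)
})

test_that("the crystallized 15-mers pair as a 14-bp core with 5' overhangs", {
  s <- crystal_duplex_structure()
  e <- extract_duplex(s, c("A", "B"))
  expect_equal(e$sense_sequence, "TGAGCTAATTAAAGC")
  expect_equal(e$antisense_sequence, "AGCTTTAATTAGCTC")
  expect_equal(nrow(e$pairing), 14)
  expect_equal(e$overhangs$sense, 1)       # 5' T of the sense strand
  expect_equal(e$overhangs$antisense, 1)   # 5' A of the antisense strand
})

test_that("extract_duplex rejects protein chains and pair-free inputs", {
  path <- withr::local_tempfile(fileext = ".pdb")
  three_atom_pdb(path)
  prot <- read_structure(path)
  expect_error(extract_duplex(prot, c("A", "A")), "not a nucleic")
})

test_that("MEME-minimal motifs read with renormalization contract", {
  path <- withr::local_tempfile(fileext = ".txt")
  consensus <- rbind(c(0, 0, 0, 1), c(1, 0, 0, 0), c(1, 0, 0, 0), c(0, 0, 0, 1))
  meme_minimal_text(path, consensus)
  m <- read_motif(path)
  expect_equal(colnames(m$mat)[apply(m$mat, 1, which.max)],
               c("T", "A", "A", "T"))

  half <- consensus * 0.5  # rows sum to 0.5 -> renormalized with warning
  meme_minimal_text(path, half)
  expect_warning(m2 <- read_motif(path), "renormalized")
  expect_equal(rowSums(m2$mat), rep(1, 4))

  meme_minimal_text(path, rbind(c(-0.1, 0.4, 0.4, 0.3)))
  expect_error(suppressWarnings(read_motif(path)), "negative")
  meme_minimal_text(path, rbind(c(0, 0, 0, 0)))
  expect_error(suppressWarnings(read_motif(path)), "zero")
})

test_that("a 15-column dimer matrix exposes spacer positions 5-11", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_motif(dimer_pwm(), path)
  m <- read_motif(path)
  expect_equal(nrow(m$mat), 15)
  sp <- dimer_site()
  expect_equal(hdcoop:::spacer_motif_positions(sp), 5:11)
  # spacer columns are near-uniform, half-site columns are not
  expect_true(all(abs(m$mat[5:11, ] - 0.25) < 1e-3))
  expect_true(all(apply(m$mat[c(1:4, 12:15), ], 1, max) > 0.8))
})

test_that("HOMER motif text parses", {
  path <- withr::local_tempfile(fileext = ".motif")
  writeLines(c(">TAAT\ttest-homer\t5.0",
               "0.02\t0.02\t0.02\t0.94",
               "0.94\t0.02\t0.02\t0.02",
               "0.94\t0.02\t0.02\t0.02",
               "0.02\t0.02\t0.02\t0.94"), path)
  m <- read_motif(path)
  expect_equal(m$name, "test-homer")
  expect_equal(colnames(m$mat)[apply(m$mat, 1, which.max)],
               c("T", "A", "A", "T"))
})

test_that("FASTA/FASTQ readers stream records; empty FASTQ is not an error", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  file.create(fq)
  expect_equal(nrow(read_reads(fq)), 0)

  fa <- withr::local_tempfile(fileext = ".fasta")
  recs <- data.frame(id = c("r1", "r2"), sequence = c("ACGT", "TTAA"))
  write_reads(recs, fa)
  back <- read_reads(fa)
  expect_equal(back$sequence, recs$sequence)
  expect_equal(back$id, recs$id)
})

test_that("intensity tables type-check and flag the background lane", {
  path <- withr::local_tempfile(fileext = ".tsv")
  five_lane_tsv(path)
  tab <- read_intensity_table(path)
  expect_equal(nrow(tab), 5)
  expect_equal(attr(tab, "background_lane"), 1)
  expect_equal(attr(tab, "probe_nM"), 35)

  bad <- read.delim(path)
  bad$monomer[2] <- -5
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_intensity_table(path), "negative band signal")

  bad2 <- read.delim(path)
  bad2$monomer <- NULL
  write.table(abs(bad2), path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_intensity_table(path), "missing required column")
})

test_that("titration tables round-trip with their protocol header", {
  iso <- one_site_heats(titration_protocol(), 1e7, -6, 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_titration(iso, path)
  back <- read_titration(path)
  expect_equal(back$heat_ucal, iso$heat_ucal, tolerance = 1e-6)
  expect_equal(back$protocol$cell_uM, 10)
  expect_equal(back$molar_ratio, iso$molar_ratio, tolerance = 1e-6)
})
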