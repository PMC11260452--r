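# Standard-reference-frame base geometries: heavy-atom coordinates of the
# four bases (plus C1') expressed in the base-pair reference frame, x toward
# the major groove, y toward the sense-strand backbone, z along the helix.
# The complementary base of a Watson-Crick pair maps onto this frame by a
# 180-degree rotation about x. Values follow the community standard
# idealized base geometries to ~1e-3 Angstrom.

STD_BASE_COORDS <- list(
  A = rbind(
    "C1'" = c(-2.479, 5.346, 0.000),
    N9 = c(-1.291, 4.498, 0.000),
    C8 = c(0.024, 4.897, 0.000),
    N7 = c(0.877, 3.902, 0.000),
    C5 = c(0.071, 2.771, 0.000),
    C6 = c(0.369, 1.398, 0.000),
    N6 = c(1.611, 0.909, 0.000),
    N1 = c(-0.668, 0.532, 0.000),
    C2 = c(-1.912, 1.023, 0.000),
    N3 = c(-2.320, 2.290, 0.000),
    C4 = c(-1.267, 3.124, 0.000)
  ),
  G = rbind(
    "C1'" = c(-2.477, 5.399, 0.000),
    N9 = c(-1.289, 4.551, 0.000),
    C8 = c(0.023, 4.962, 0.000),
    N7 = c(0.870, 3.969, 0.000),
    C5 = c(0.071, 2.833, 0.000),
    C6 = c(0.424, 1.460, 0.000),
    O6 = c(1.554, 0.955, 0.000),
    N1 = c(-0.700, 0.641, 0.000),
    C2 = c(-1.999, 1.087, 0.000),
    N2 = c(-2.949, 0.139, -0.001),
    N3 = c(-2.342, 2.364, 0.001),
    C4 = c(-1.265, 3.177, 0.000)
  ),
  C = rbind(
    "C1'" = c(-2.477, 5.402, 0.000),
    N1 = c(-1.285, 4.542, 0.000),
    C2 = c(-1.472, 3.158, 0.000),
    O2 = c(-2.628, 2.709, 0.001),
    N3 = c(-0.391, 2.344, 0.000),
    C4 = c(0.837, 2.868, 0.000),
    N4 = c(1.875, 2.027, 0.001),
    C5 = c(1.056, 4.275, 0.000),
    C6 = c(-0.023, 5.068, 0.000)
  ),
  T = rbind(
    "C1'" = c(-2.481, 5.354, 0.000),
    N1 = c(-1.284, 4.500, 0.000),
    C2 = c(-1.462, 3.135, 0.000),
    O2 = c(-2.562, 2.608, 0.000),
    N3 = c(-0.298, 2.407, 0.000),
    C4 = c(0.994, 2.897, 0.000),
    O4 = c(1.944, 2.119, 0.000),
    C5 = c(1.106, 4.338, 0.000),
    C7 = c(2.466, 4.961, 0.001),
    C6 = c(-0.024, 5.057, 0.000)
  )
)

# Backbone phosphorus position in the base-pair frame for the sense-strand
# nucleotide (cylindrical radius 8.91 A, azimuth 121 deg, height 1.25 A),
# calibrated so an ideal B-form build reproduces canonical fiber geometry:
# minor-groove cross-strand P-P ~11.6 A and major ~17.1 A at the groove
# registers used in groove_profile(). The antisense phosphate is the
# 180-degree-about-x image.
P_LOCAL <- c(8.91 * cos(121 * pi / 180), 8.91 * sin(121 * pi / 180), 1.25)

IDEAL_B_TWIST <- 36.0
IDEAL_B_RISE <- 3.38

# Minor-groove width convention: cross-strand P-P distance minus two
# phosphate van der Waals radii.
PHOSPHATE_VDW_CORRECTION <- 5.8

load_step_table <- function() {
  path <- system.file("extdata", "bdna_step_params.tsv", package = "hdcoop")
  if (path == "") path <- file.path("inst", "extdata", "bdna_step_params.tsv")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  # expand to all 16 dinucleotides via strand symmetry: the step of the
  # reverse complement has the same roll/twist/rise, mirrored tilt/shift.
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  extra <- tab[vapply(tab$step, rc, character(1)) != tab$step, , drop = FALSE]
  if (nrow(extra) > 0) {
    mirrored <- extra
    mirrored$step <- vapply(extra$step, rc, character(1))
    mirrored$tilt <- -extra$tilt
    mirrored$shift <- -extra$shift
    tab <- rbind(tab, mirrored)
  }
  tab <- tab[!duplicated(tab$step), , drop = FALSE]
  rownames(tab) <- tab$step
  tab
}
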