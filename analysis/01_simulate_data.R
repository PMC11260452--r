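#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs used by the downstream
# analysis scripts - SELEX read libraries under selection, EMSA intensity
# tables for the cooperative and non-cooperative conditions, a clean ITC
# isotherm under the study protocol, and toy bent/straight monomer
# complexes for the dimer modeler.

suppressMessages(library(hdcoop))
dir.create("results/simulated", recursive = TRUE, showWarnings = FALSE)

message("SELEX libraries (5 cycles, 2000 reads each) ...")
selex <- gen_selex(seed = 1001, n_cycles = 4, n_reads = 2000)
for (cyc in names(selex)) {
  write_reads(selex[[cyc]], file.path("results/simulated",
                                      paste0(cyc, ".fasta")))
}

message("EMSA tables: omega = 38 (7-bp spacer) and omega = 2 (8-bp) ...")
for (i in 1:3) {
  write_intensity_table(
    gen_emsa(seed = 2000 + i, omega = 38),
    file.path("results/simulated", sprintf("emsa_7bpS_rep%d.tsv", i)))
  write_intensity_table(
    gen_emsa(seed = 2100 + i, omega = 2),
    file.path("results/simulated", sprintf("emsa_8bpS_rep%d.tsv", i)))
}

message("ITC isotherm (K = 6.8e7, dH = -5.4, n = 1.02, clean) ...")
write_titration(gen_itc(seed = 3001), "results/simulated/itc_taatta.tsv")

message("Toy monomer complexes (bend 20 and 0 degrees) ...")
write_structure(gen_toy_complex(bend_deg = 20),
                "results/simulated/toy_complex_bent.pdb")
write_structure(gen_toy_complex(bend_deg = 0),
                "results/simulated/toy_complex_straight.pdb")

message("done: results/simulated/")
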