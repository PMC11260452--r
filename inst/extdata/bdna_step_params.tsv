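# Sequence-dependent B-DNA dinucleotide step parameters, version 1.
# Mean rigid-body step parameters (degrees, Angstrom) in the style of
# crystallographic survey averages, with per-step propeller twist of the
# flanking base pairs. The table is strand-symmetric: a step and its
# reverse complement share one row. Swap this file to change the model.
step	shift	slide	rise	tilt	roll	twist	propeller
AA	0	0	3.32	0	0.5	35.8	-16.5
AT	0	0	3.32	0	-0.6	33.4	-14.0
AG	0	0	3.36	0	3.5	34.0	-11.0
AC	0	0	3.36	0	1.0	34.3	-11.5
GA	0	0	3.36	0	1.5	36.9	-10.5
GG	0	0	3.40	0	4.6	33.7	-9.0
GC	0	0	3.40	0	2.0	36.1	-8.5
CA	0	0	3.36	0	5.5	34.5	-9.5
CG	0	0	3.40	0	6.5	29.8	-8.0
TA	0	0	3.32	0	2.5	36.0	-12.5
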