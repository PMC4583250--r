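# Per-gene distinct-variant counts and reported enrichment rates of the
# bundled reference study (436 haploid mtDNA samples). rg in variants/Mb,
# rw as printed by the study (numerically a per-bp carrier-sum rate).
symbol	biotype	length	n_variants	rg	rw
MT-RNR1	Mt_rRNA	955	34	35.6	1.07
MT-RNR2	Mt_rRNA	1561	57	37.2	0.64
MT-ND1	protein_coding	957	58	60.6	0.27
MT-ND2	protein_coding	1043	64	61.4	0.62
MT-CO1	protein_coding	1543	98	63.5	0.29
MT-CO2	protein_coding	685	44	64.2	0.11
MT-ATP8	protein_coding	208	15	72.1	0.12
MT-ATP6	protein_coding	682	59	86.5	0.92
MT-CO3	protein_coding	785	60	76.4	0.23
MT-ND3	protein_coding	347	24	69.2	0.30
MT-ND4L	protein_coding	298	20	67.1	0.23
MT-ND4	protein_coding	1379	85	61.6	0.46
MT-ND5	protein_coding	1813	134	73.9	0.27
MT-ND6	protein_coding	526	26	49.4	0.24
MT-CYB	protein_coding	1142	96	84.1	0.91
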