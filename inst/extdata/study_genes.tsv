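# Gene model of the bundled reference study: 15 non-tRNA mitochondrial genes.
# Coordinates/strands: standard rCRS (NC_012920.1) heavy-strand annotation.
# length: the study's reported gene lengths, carried verbatim (enrichment denominators).
symbol	biotype	start	end	strand	length
MT-RNR1	Mt_rRNA	648	1601	+	955
MT-RNR2	Mt_rRNA	1671	3229	+	1561
MT-ND1	protein_coding	3307	4262	+	957
MT-ND2	protein_coding	4470	5511	+	1043
MT-CO1	protein_coding	5904	7445	+	1543
MT-CO2	protein_coding	7586	8269	+	685
MT-ATP8	protein_coding	8366	8572	+	208
MT-ATP6	protein_coding	8527	9207	+	682
MT-CO3	protein_coding	9207	9990	+	785
MT-ND3	protein_coding	10059	10404	+	347
MT-ND4L	protein_coding	10470	10766	+	298
MT-ND4	protein_coding	10760	12137	+	1379
MT-ND5	protein_coding	12337	14148	+	1813
MT-ND6	protein_coding	14149	14673	-	526
MT-CYB	protein_coding	14747	15887	+	1142
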