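# The reference study's 35 variants absent from the known-variant catalog
# (32 substitutions, 3 indels); every one observed once except 3385 (twice).
position	ref	alt	conserved	gene	effect	sift	polyphen	carrier_count
393	T	A	No	NA	intergenic	NA	NA	1
1713	A	G	No	MT-RNR2	non_coding	NA	NA	1
1807	T	C	No	MT-RNR2	non_coding	NA	NA	1
2150	T	TA	Yes	MT-RNR2	non_coding	NA	NA	1
2156	A	AT	No	MT-RNR2	non_coding	NA	NA	1
3385	A	T	No	MT-ND1	missense	deleterious	possibly_damaging	2
4875	C	T	No	MT-ND2	synonymous	NA	NA	1
5573	A	G	No	MT-TW	non_coding	NA	NA	1
5746	GA	G	No	NA	intergenic	NA	NA	1
6113	A	T	No	MT-CO1	synonymous	NA	NA	1
6200	C	T	No	MT-CO1	synonymous	NA	NA	1
6569	C	T	No	MT-CO1	synonymous	NA	NA	1
6608	C	T	No	MT-CO1	synonymous	NA	NA	1
6812	A	G	No	MT-CO1	synonymous	NA	NA	1
7004	A	G	No	MT-CO1	synonymous	NA	NA	1
7366	C	T	Yes	MT-CO1	missense	tolerated	benign	1
8263	C	T	No	MT-CO2	synonymous	NA	NA	1
8465	C	T	No	MT-ATP8	missense	tolerated	probably_damaging	1
8673	A	G	No	MT-ATP6	synonymous	NA	NA	1
9138	C	T	No	MT-ATP6	synonymous	NA	NA	1
9370	A	T	No	MT-CO3	missense	tolerated	benign	1
9500	C	A	No	MT-CO3	missense	deleterious	probably_damaging	1
9577	T	C	Yes	MT-CO3	missense	deleterious	probably_damaging	1
9873	C	A	No	MT-CO3	missense	tolerated	probably_damaging	1
9890	A	G	No	MT-CO3	synonymous	NA	NA	1
10030	C	T	No	MT-TG	non_coding	NA	NA	1
10094	C	A	No	MT-ND3	synonymous	NA	NA	1
12098	C	T	No	MT-ND4	synonymous	NA	NA	1
12266	A	G	No	MT-TL2	non_coding	NA	NA	1
13380	C	T	No	MT-ND5	synonymous	NA	NA	1
13792	C	T	No	MT-ND5	synonymous	NA	NA	1
13806	C	T	No	MT-ND5	synonymous	NA	NA	1
15620	C	T	Yes	MT-CYB	missense	deleterious	possibly_damaging	1
16229	T	A	No	NA	intergenic	NA	NA	1
16454	C	T	No	NA	intergenic	NA	NA	1
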