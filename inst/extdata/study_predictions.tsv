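# SIFT/PolyPhen categorical predictions printed in the reference study's tables.
position	ref	alt	sift	polyphen
3388	C	A	deleterious	probably_damaging
6237	C	A	deleterious	probably_damaging
6489	C	A	deleterious	probably_damaging
7941	A	G	deleterious	probably_damaging
7964	T	C	deleterious	probably_damaging
7976	G	A	deleterious	probably_damaging
8563	A	G	deleterious	probably_damaging
8839	G	A	deleterious	probably_damaging
8920	G	A	deleterious	probably_damaging
9010	G	A	deleterious	probably_damaging
9448	A	G	deleterious	probably_damaging
9500	C	A	deleterious	probably_damaging
9577	T	C	deleterious	probably_damaging
9903	T	C	deleterious	probably_damaging
11087	T	C	deleterious	probably_damaging
12634	A	G	deleterious	probably_damaging
12923	G	T	deleterious	probably_damaging
13129	C	T	deleterious	probably_damaging
13973	A	T	deleterious	probably_damaging
14180	T	C	deleterious	probably_damaging
14484	T	C	deleterious	probably_damaging
14769	A	G	deleterious	probably_damaging
15218	A	G	deleterious	probably_damaging
15773	G	A	deleterious	probably_damaging
3385	A	T	deleterious	possibly_damaging
7366	C	T	tolerated	benign
8465	C	T	tolerated	probably_damaging
9370	A	T	tolerated	benign
9873	C	A	tolerated	probably_damaging
15620	C	T	deleterious	possibly_damaging
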