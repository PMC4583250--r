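# Known-variant catalog fixture: exactly the keys the reference study's
# tables mark as catalog-Known (a stand-in for a MITOMAP extract).
position	ref	alt
3388	C	A
6237	C	A
6489	C	A
7941	A	G
7964	T	C
7976	G	A
8563	A	G
8839	G	A
8920	G	A
9010	G	A
9448	A	G
9903	T	C
11087	T	C
12634	A	G
12923	G	T
13129	C	T
13973	A	T
14180	T	C
14484	T	C
14769	A	G
15218	A	G
15773	G	A
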