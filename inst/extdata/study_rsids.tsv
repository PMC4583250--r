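# rsIDs printed in the reference study's tables.
position	ref	alt	rsid
6489	C	A	rs28461189
9903	T	C	rs199999390
14769	A	G	rs28357679
15218	A	G	rs2853506
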