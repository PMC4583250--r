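# Vertebrate-conserved positions flagged in the reference study's tables.
2150
6489
7366
7941
7976
8839
9010
9448
9577
9903
11087
12634
13129
14769
15620
15773
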