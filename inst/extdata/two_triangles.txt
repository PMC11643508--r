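# one closed and one bare 3-edge: SF 1/2, ES 1/2, FES 1/2
1 2 3
4 5 6
1 2
1 3
2 3
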