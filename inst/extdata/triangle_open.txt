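# a 3-edge with a single pair: SF 0, ES 1/3, FES 1/3
1 2 3
1 2
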