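# excitation counts per b-value of protocol.bval
nex: 1 3 3 3 3 2 2 2 2 3 5 6
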