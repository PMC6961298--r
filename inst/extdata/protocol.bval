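0 10 25 50 75 100 150 200 400 800 1000 1500
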