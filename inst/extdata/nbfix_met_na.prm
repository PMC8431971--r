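NBFIX
S      SOD    -13.4 2.8
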