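NONBONDED
CT3    0.0 -0.0780 2.04000
CT2    0.0 -0.0560 2.01000
HA     0.0 -0.0240 1.34000
HS     0.0 -0.1000 0.45000
S      0.0 -0.4500 2.00000
SOD    0.0 -0.0469 1.41075

CHARGES
methylthioethane   SD     -0.09
methylthioethane   C3     -0.22
methylthioethane   C2     -0.14
methylthioethane   C1     -0.27
methylthioethane   H31    0.09
methylthioethane   H32    0.09
methylthioethane   H33    0.09
methylthioethane   H21    0.09
methylthioethane   H22    0.09
methylthioethane   H11    0.09
methylthioethane   H12    0.09
methylthioethane   H13    0.09
methanethiol       SG     -0.23
methanethiol       C1     -0.20
methanethiol       HG     0.16
methanethiol       H11    0.09
methanethiol       H12    0.09
methanethiol       H13    0.09
END
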