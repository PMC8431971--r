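6
methanethiol
S      0.000000     0.000000     0.000000  SG   S   
C      1.810000     0.000000     0.000000  C1   CT3 
H     -0.140068     1.332659     0.000000  HG   HS  
H      2.182802     0.512132     0.887039  H11  HA  
H      2.182802    -1.024265     0.000000  H12  HA  
H      2.182802     0.512132    -0.887039  H13  HA  
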