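12
methylthioethane
S      0.000000     0.000000     0.000000  SD   S   
C      1.810000     0.000000     0.000000  C3   CT3 
C     -0.280026     1.788207     0.000000  C2   CT2 
C     -1.757199     2.186779    -0.000000  C1   CT3 
H      2.182802     0.512132     0.887039  H31  HA  
H      2.182802    -1.024265     0.000000  H32  HA  
H      2.182802     0.512132    -0.887039  H33  HA  
H     -0.843668     2.077289    -0.887039  H21  HA  
H     -0.843668     2.077289     0.887039  H22  HA  
H     -2.250542     1.789446     0.887039  H11  HA  
H     -1.850303     3.272796    -0.000000  H12  HA  
H     -2.250542     1.789446    -0.887039  H13  HA  
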