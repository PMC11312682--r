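     6  meoh generated by MMFF94 local optimization
     1  C    -0.371029    0.007261   -0.009452     CA 2 3 4 5
     2  O     0.918135   -0.502580   -0.296547     OH 1 6
     3  H    -0.522731    0.028690    1.072513     HA 1
     4  H    -0.465369    1.014980   -0.421427     HA 1
     5  H    -1.120319   -0.642747   -0.467354     HA 1
     6  H     1.561313    0.094397    0.122267     HO 2
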