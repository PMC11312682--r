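     3  h2o generated by MMFF94 local optimization
     1  O     0.007544    0.397743    0.000000     OW 2 3
     2  H    -0.767103   -0.184393    0.000000     HW 1
     3  H     0.759559   -0.213350    0.000000     HW 1
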