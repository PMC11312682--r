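     9  me2o generated by MMFF94 local optimization
     1  C    -1.168191   -0.002702   -0.404053     CS 2 4 5 6
     2  O    -0.026714    0.839290   -0.315816     OS 1 3
     3  C     1.165550    0.085665   -0.141863     CS 2 7 8 9
     4  H    -2.051827    0.627311   -0.536561     HS 1
     5  H    -1.084258   -0.672845   -1.265092     HS 1
     6  H    -1.287694   -0.583654    0.515588     HS 1
     7  H     1.121349   -0.492440    0.786234     HS 3
     8  H     2.007003    0.780997   -0.080557     HS 3
     9  H     1.324783   -0.581623   -0.994445     HS 3
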