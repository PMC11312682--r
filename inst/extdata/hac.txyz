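     8  hac generated by MMFF94 local optimization
     1  C    -0.933543   -0.060063   -0.230376     CX 2 5 6 7
     2  C     0.493608    0.278933    0.046914     CC 1 3 4
     3  O     1.032525    1.356629   -0.136136     OC 2
     4  O     1.181401   -0.764470    0.546212     OA 2 8
     5  H    -1.442687    0.820299   -0.632706     HC 1
     6  H    -1.430457   -0.357583    0.696271     HC 1
     7  H    -0.986731   -0.862547   -0.970180     HC 1
     8  H     2.085884   -0.411198    0.680001     HQ 4
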