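     8  et generated by MMFF94 local optimization
     1  C    -0.755815    0.007100   -0.016504     CE 2 3 4 5
     2  C     0.755816   -0.007100    0.016504     CE 1 6 7 8
     3  H    -1.163351   -0.100381    0.993141     HC 1
     4  H    -1.122263    0.948089   -0.437543     HC 1
     5  H    -1.134621   -0.815581   -0.630281     HC 1
     6  H     1.134621    0.815583    0.630279     HC 2
     7  H     1.163351    0.100379   -0.993141     HC 2
     8  H     1.122263   -0.948088    0.437545     HC 2
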