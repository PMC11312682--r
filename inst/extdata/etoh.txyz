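     9  etoh generated by MMFF94 local optimization
     1  C    -0.888311    0.167003   -0.027316     CE 2 4 5 6
     2  C     0.465753   -0.511559   -0.036795     CA 1 3 7 8
     3  O     1.431075    0.322916    0.586670     OH 2 9
     4  H    -0.848741    1.117480   -0.569524     HC 1
     5  H    -1.647121   -0.470443   -0.489637     HC 1
     6  H    -1.196397    0.397845    0.997723     HC 1
     7  H     0.791997   -0.722428   -1.059726     HC 2
     8  H     0.424604   -1.455862    0.513791     HC 2
     9  H     1.467142    1.155048    0.084814     HO 3
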