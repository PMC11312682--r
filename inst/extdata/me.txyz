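     5  me generated by MMFF94 local optimization
     1  C    -0.000000   -0.000000   -0.000000     CM 2 3 4 5
     2  H    -0.675343    0.854123   -0.085361     HC 1
     3  H    -0.394946   -0.835938   -0.581485     HC 1
     4  H     0.084754   -0.293741    1.048538     HC 1
     5  H     0.985535    0.275556   -0.381692     HC 1
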