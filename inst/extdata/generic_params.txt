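# Generic Lennard-Jones 12-6 + point-charge parameter table for the bundled
# fixture molecules. Columns: atom type label, sigma [Angstrom],
# epsilon [kcal/mol], partial charge [e]. OPLS-AA-flavoured values; water is
# TIP3P. Lines starting with '#' are comments.
# type  sigma    epsilon  charge
OW      3.15061  0.1521  -0.834
HW      0.000    0.000    0.417
CM      3.50     0.066   -0.240
HC      2.50     0.030    0.060
CE      3.50     0.066   -0.180
CA      3.50     0.066    0.145
HA      2.50     0.030    0.040
OH      3.12     0.170   -0.683
HO      0.000    0.000    0.418
OS      3.00     0.170   -0.400
CS      3.50     0.066    0.110
HS      2.50     0.030    0.030
CC      3.75     0.105    0.520
OC      2.96     0.210   -0.440
OA      3.00     0.170   -0.530
HQ      0.000    0.000    0.450
CX      3.50     0.066   -0.180
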