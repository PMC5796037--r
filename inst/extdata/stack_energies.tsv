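dinucleotide	energy_kcal_mol
AA	-0.9
AC	-2.1
AG	-1.7
AU	-1.1
CA	-2.0
CC	-3.3
CG	-2.4
CU	-1.8
GA	-2.1
GC	-3.4
GG	-3.3
GU	-2.2
UA	-1.3
UC	-2.1
UG	-1.4
UU	-0.9
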