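element	vdw	covalent
H	1.20	0.31
B	1.92	0.84
C	1.70	0.76
N	1.55	0.71
O	1.52	0.66
F	1.47	0.57
Na	2.27	1.66
Mg	1.73	1.41
Si	2.10	1.11
P	1.80	1.07
S	1.80	1.05
Cl	1.75	1.02
K	2.75	2.03
Ca	2.31	1.76
Mn	2.05	1.39
Fe	2.04	1.32
Co	2.00	1.26
Ni	1.97	1.24
Cu	1.96	1.32
Zn	2.01	1.22
Se	1.90	1.20
Br	1.85	1.20
I	1.98	1.39
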