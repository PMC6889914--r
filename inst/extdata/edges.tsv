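element	edge	energy_kev
C	K	0.2842
N	K	0.4099
O	K	0.5431
S	K	2.472
Cl	K	2.8224
Zn	K	9.6586
I	K	33.1694
I	L_I	5.1881
I	L_II	4.8521
I	L_III	4.5571
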