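element	a1	a2	a3	a4	b1	b2	b3	b4	c
C	2.310000	1.020000	1.588600	0.865000	20.843900	10.207500	0.568700	51.651200	0.215600
N	12.212600	3.132200	2.012500	1.166300	0.005700	9.893300	28.997500	0.582600	-11.529000
O	3.048500	2.286800	1.546300	0.867000	13.277100	5.701100	0.323900	32.908900	0.250800
S	6.905300	5.203400	1.437900	1.586300	1.467900	22.215100	0.253600	56.172000	0.866900
Cl	11.460400	7.196400	6.255600	1.645500	0.010400	1.166200	18.519400	47.778400	-9.557400
Zn	14.074300	7.031800	5.165200	2.410000	3.265500	0.233300	10.316300	58.709700	1.304100
I	20.147200	18.994900	7.513800	2.273500	4.347000	0.381400	27.766000	66.877600	4.071200
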