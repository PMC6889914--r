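element	energy_kev	f_prime	f_double_prime
C	2.3000	0.1331	0.1230
C	2.5000	0.1188	0.1043
C	2.7000	0.1066	0.0895
C	2.9000	0.0962	0.0775
C	3.1000	0.0873	0.0678
C	3.3000	0.0795	0.0596
C	3.6000	0.0697	0.0499
C	3.9000	0.0615	0.0423
C	4.2000	0.0547	0.0363
C	4.5000	0.0490	0.0314
C	4.8000	0.0441	0.0274
C	5.0000	0.0412	0.0252
C	5.2000	0.0386	0.0232
C	5.4000	0.0364	0.0214
C	5.6000	0.0342	0.0198
C	5.8000	0.0322	0.0184
C	6.0000	0.0303	0.0171
C	6.2000	0.0287	0.0159
N	2.3000	0.2030	0.2307
N	2.5000	0.1835	0.1965
N	2.7000	0.1665	0.1693
N	2.9000	0.1517	0.1472
N	3.1000	0.1388	0.1290
N	3.3000	0.1274	0.1139
N	3.6000	0.1127	0.0957
N	3.9000	0.1003	0.0814
N	4.2000	0.0899	0.0701
N	4.5000	0.0810	0.0609
N	4.8000	0.0733	0.0533
N	5.0000	0.0688	0.0490
N	5.2000	0.0647	0.0452
N	5.4000	0.0609	0.0418
N	5.6000	0.0574	0.0388
N	5.8000	0.0543	0.0360
N	6.0000	0.0513	0.0336
N	6.2000	0.0486	0.0313
O	2.3000	0.2768	0.3900
O	2.5000	0.2545	0.3336
O	2.7000	0.2342	0.2884
O	2.9000	0.2159	0.2517
O	3.1000	0.1995	0.2213
O	3.3000	0.1848	0.1960
O	3.6000	0.1654	0.1653
O	3.9000	0.1487	0.1412
O	4.2000	0.1344	0.1218
O	4.5000	0.1220	0.1062
O	4.8000	0.1112	0.0933
O	5.0000	0.1047	0.0859
O	5.2000	0.0988	0.0793
O	5.4000	0.0934	0.0735
O	5.6000	0.0884	0.0683
O	5.8000	0.0837	0.0635
O	6.0000	0.0795	0.0593
O	6.2000	0.0755	0.0554
S	2.3000	-2.7633	0.4343
S	2.4680	-6.9465	0.3841
S	2.4760	-6.9220	4.1009
S	2.5000	-4.5544	4.0515
S	2.7000	-1.8011	3.6186
S	2.9000	-1.0000	3.2288
S	3.1000	-0.5559	2.9046
S	3.3000	-0.2721	2.6282
S	3.6000	-0.0064	2.2819
S	3.9000	0.1530	2.0000
S	4.2000	0.2518	1.7673
S	4.5000	0.3150	1.5728
S	4.8000	0.3528	1.4084
S	5.0000	0.3731	1.3124
S	5.2000	0.3834	1.2253
S	5.4000	0.3896	1.1465
S	5.6000	0.3925	1.0750
S	5.8000	0.3931	1.0100
S	6.0000	0.3917	0.9507
S	6.2000	0.3888	0.8964
Cl	2.3000	-1.7868	0.5658
Cl	2.5000	-2.2263	0.4897
Cl	2.7000	-3.1753	0.4282
Cl	2.8184	-6.9990	0.3972
Cl	2.8264	-6.9771	4.0881
Cl	2.9000	-3.3440	3.9471
Cl	3.1000	-1.6758	3.5572
Cl	3.3000	-0.9945	3.2225
Cl	3.6000	-0.4440	2.8038
Cl	3.9000	-0.1342	2.4635
Cl	4.2000	0.0571	2.1820
Cl	4.5000	0.1803	1.9461
Cl	4.8000	0.2612	1.7465
Cl	5.0000	0.2991	1.6299
Cl	5.2000	0.3288	1.5245
Cl	5.4000	0.3501	1.4289
Cl	5.6000	0.3656	1.3419
Cl	5.8000	0.3795	1.2621
Cl	6.0000	0.3865	1.1891
Cl	6.2000	0.3907	1.1222
Zn	2.3000	-0.1023	5.7885
Zn	2.5000	0.0022	5.0663
Zn	2.7000	0.0425	4.4733
Zn	2.9000	0.0443	3.9804
Zn	3.1000	0.0224	3.5645
Zn	3.3000	-0.0152	3.2105
Zn	3.6000	-0.0889	2.7728
Zn	3.9000	-0.1722	2.4205
Zn	4.2000	-0.2605	2.1326
Zn	4.5000	-0.3459	1.8939
Zn	4.8000	-0.4337	1.6930
Zn	5.0000	-0.4933	1.5767
Zn	5.2000	-0.5496	1.4722
Zn	5.4000	-0.6089	1.3777
Zn	5.6000	-0.6680	1.2923
Zn	5.8000	-0.7273	1.2147
Zn	6.0000	-0.7869	1.1440
Zn	6.2000	-0.8473	1.0795
I	2.3000	-4.7147	9.4902
I	2.5000	-4.7813	8.4100
I	2.7000	-4.9373	7.5086
I	2.9000	-5.1639	6.7502
I	3.1000	-5.4477	6.1017
I	3.3000	-5.7961	5.5437
I	3.6000	-6.4545	4.8455
I	3.9000	-7.3943	4.2743
I	4.2000	-8.9402	3.8022
I	4.5000	-13.4567	3.4200
I	4.5531	-19.8437	3.3446
I	4.5611	-19.8417	10.9120
I	4.8000	-11.6800	9.7696
I	4.8481	-14.2675	9.6104
I	4.8561	-14.1955	13.3500
I	5.0000	-8.9789	12.6406
I	5.1841	-9.3517	11.8694
I	5.1921	-9.2881	13.6649
I	5.2000	-8.5916	13.4100
I	5.4000	-5.6553	12.8739
I	5.6000	-4.3878	12.1765
I	5.8000	-3.5022	11.5350
I	6.0000	-2.8267	10.9428
I	6.2000	-2.3023	10.3946
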