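species	target_median	target_upper	target_lower	nontarget_median	nontarget_upper	nontarget_lower	rank_sum_p
amel	0.1104	0.1831	0.0555	0.1280	0.2426	0.0608	7.03e-07
btau	0.1028	0.1851	0.0535	0.1246	0.2344	0.0564	7.93e-06
cfam	0.1057	0.1857	0.0576	0.1270	0.2408	0.0591	2.94e-06
cjac	0.1584	0.2733	0.0779	0.1893	0.3575	0.0838	9.80e-07
cpor	0.1026	0.1800	0.0534	0.1211	0.2247	0.0578	3.11e-06
ecab	0.1177	0.1984	0.0613	0.1352	0.2528	0.0595	5.50e-05
itri	0.1027	0.1817	0.0538	0.1181	0.2212	0.0487	0.0063
lafr	0.1173	0.1990	0.0645	0.1400	0.2551	0.0684	4.43e-07
mdom	0.0757	0.1308	0.0425	0.0943	0.1692	0.0451	3.08e-08
mfur	0.0975	0.1736	0.0502	0.1233	0.2235	0.0537	5.02e-07
mluc	0.1281	0.2104	0.0684	0.1407	0.2547	0.0693	0.00172
mmul	0.1578	0.2966	0.0709	0.1970	0.3870	0.0730	2.12e-06
mmus	0.0910	0.1558	0.0479	0.1125	0.2100	0.0497	4.12e-09
nleu	0.1735	0.3260	0.0781	0.2235	0.4261	0.0881	1.94e-08
ocun	0.1014	0.1662	0.0510	0.1178	0.2184	0.0570	1.84e-07
ogar	0.1163	0.1950	0.0604	0.1395	0.2482	0.0593	5.43e-06
pabe	0.1561	0.3096	0.0743	0.2022	0.4018	0.0792	1.70e-07
ptro	0.1718	0.3559	0.0578	0.2184	0.4715	0.0574	2.73e-06
rnor	0.0931	0.1616	0.0487	0.1159	0.2105	0.0521	6.80e-08
shar	0.0756	0.1326	0.0426	0.0938	0.1676	0.0451	4.92e-08
sscr	0.1130	0.1944	0.0585	0.1321	0.2378	0.0595	0.0006
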