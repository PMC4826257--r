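species	target_median	target_upper	target_lower	nontarget_median	nontarget_upper	nontarget_lower	rank_sum_p
amel	838.00	1213.00	548.00	613.00	957.00	361.00	2.44e-34
btau	840.00	1257.50	571.50	615.00	965.00	373.50	6.18e-38
cfam	859.00	1279.00	557.25	622.00	988.00	371.00	1.11e-34
cjac	905.00	1299.50	620.00	655.00	1054.25	394.00	3.59e-37
cpor	828.00	1221.00	545.00	587.00	919.50	352.00	1.83e-40
ecab	845.00	1228.00	552.50	608.00	952.00	360.25	3.47e-36
itri	817.50	1153.00	553.25	594.00	909.00	367.50	1.47e-36
lafr	831.50	1205.25	555.00	591.50	926.00	359.00	9.60e-41
mdom	773.00	1135.75	472.00	514.50	808.25	314.00	1.37e-41
mfur	856.50	1238.75	576.00	636.00	981.25	389.00	5.23e-33
mluc	823.50	1197.00	525.00	582.00	925.00	354.00	4.33e-32
mmul	895.00	1315.75	613.00	644.00	1023.50	390.00	1.04e-41
mmus	852.00	1271.50	565.00	602.00	932.00	361.00	1.81e-46
nleu	900.00	1290.50	610.00	669.00	1064.00	403.00	2.05e-31
ocun	845.00	1233.25	568.50	608.00	949.75	360.00	1.31e-37
ogar	863.00	1272.25	580.00	628.00	974.00	382.00	8.81e-40
pabe	877.00	1257.50	595.50	655.00	1038.00	399.00	3.41e-32
ptro	925.50	1332.00	611.00	682.00	1087.00	410.00	1.47e-33
rnor	804.00	1141.00	541.50	569.00	876.00	343.00	8.96e-38
shar	701.00	1007.00	432.50	499.00	796.00	305.00	3.34e-28
sscr	768.50	1098.75	482.25	565.00	876.00	328.00	2.25e-28
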