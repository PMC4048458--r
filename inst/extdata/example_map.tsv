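chr1	0	10000	0
chr1	10000	20000	2.7715
chr1	20000	30000	4e-04
chr1	30000	40000	0.3533
chr1	40000	50000	6.6755
chr1	50000	60000	1.2955
chr1	60000	70000	0.6404
chr1	70000	80000	0.2877
chr1	80000	90000	0.1205
chr1	90000	1e+05	2.9118
chr1	1e+05	110000	0.0244
chr1	110000	120000	0.8131
chr1	120000	130000	0
chr1	130000	140000	0
chr1	140000	150000	0.0602
chr1	150000	160000	0
chr1	160000	170000	0.9317
chr1	170000	180000	1.931
chr1	180000	190000	11.1342
chr1	190000	2e+05	0
chr1	2e+05	210000	0
chr1	210000	220000	3.7031
chr1	220000	230000	0
chr1	230000	240000	0.0597
chr1	240000	250000	0.1494
chr1	250000	260000	0.2147
chr1	260000	270000	0.4556
chr1	270000	280000	0
chr1	280000	290000	0
chr1	290000	3e+05	0
chr1	3e+05	310000	1.8393
chr1	310000	320000	3e-04
chr1	320000	330000	2.3167
chr1	330000	340000	0
chr1	340000	350000	0
chr1	350000	360000	0.2385
chr1	360000	370000	0.1112
chr1	370000	380000	1e-04
chr1	380000	390000	0.1748
chr1	390000	4e+05	0
chr1	4e+05	410000	0
chr1	410000	420000	0
chr1	420000	430000	0.0247
chr1	430000	440000	0
chr1	440000	450000	9.4321
chr1	450000	460000	11.1073
chr1	460000	470000	0
chr1	470000	480000	0
chr1	480000	490000	0
chr1	490000	5e+05	0
chr1	5e+05	510000	0.0485
chr1	510000	520000	1.3478
chr1	520000	530000	0
chr1	530000	540000	0
chr1	540000	550000	0
chr1	550000	560000	0
chr1	560000	570000	0.0044
chr1	570000	580000	0
chr1	580000	590000	6.9382
chr1	590000	6e+05	0.2644
chr1	6e+05	610000	0
chr1	610000	620000	2.0477
chr1	620000	630000	0
chr1	630000	640000	0
chr1	640000	650000	0
chr1	650000	660000	0.5125
chr1	660000	670000	0
chr1	670000	680000	0.1846
chr1	680000	690000	0.0672
chr1	690000	7e+05	1e-04
chr1	7e+05	710000	0
chr1	710000	720000	0.0257
chr1	720000	730000	0.0433
chr1	730000	740000	0.0782
chr1	740000	750000	0.8436
chr1	750000	760000	0.3725
chr1	760000	770000	0.9647
chr1	770000	780000	0.5644
chr1	780000	790000	0.9568
chr1	790000	8e+05	24.2399
chr1	8e+05	810000	5.9073
chr1	810000	820000	0
chr1	820000	830000	0
chr1	830000	840000	0
chr1	840000	850000	0
chr1	850000	860000	5.7378
chr1	860000	870000	0
chr1	870000	880000	0
chr1	880000	890000	5.5682
chr1	890000	9e+05	0
chr1	9e+05	910000	1.4527
chr1	910000	920000	14.3575
chr1	920000	930000	0
chr1	930000	940000	0.2104
chr1	940000	950000	3.6708
chr1	950000	960000	0
chr1	960000	970000	0
chr1	970000	980000	0
chr1	980000	990000	0.2383
chr1	990000	1e+06	0
chr1	1e+06	1010000	0
chr1	1010000	1020000	0
chr1	1020000	1030000	0.9736
chr1	1030000	1040000	10.8546
chr1	1040000	1050000	7.7569
chr1	1050000	1060000	0
chr1	1060000	1070000	0.0817
chr1	1070000	1080000	3.2556
chr1	1080000	1090000	0
chr1	1090000	1100000	0
chr1	1100000	1110000	0
chr1	1110000	1120000	0.0167
chr1	1120000	1130000	3e-04
chr1	1130000	1140000	0.0016
chr1	1140000	1150000	0
chr1	1150000	1160000	0.0758
chr1	1160000	1170000	0.0083
chr1	1170000	1180000	0
chr1	1180000	1190000	0
chr1	1190000	1200000	0
chr1	1200000	1210000	1.8775
chr1	1210000	1220000	0
chr1	1220000	1230000	0.0124
chr1	1230000	1240000	0
chr1	1240000	1250000	0
chr1	1250000	1260000	14.6137
chr1	1260000	1270000	5e-04
chr1	1270000	1280000	7.794
chr1	1280000	1290000	0.8724
chr1	1290000	1300000	0.0122
chr1	1300000	1310000	0.1136
chr1	1310000	1320000	2.3604
chr1	1320000	1330000	0
chr1	1330000	1340000	0.1529
chr1	1340000	1350000	0
chr1	1350000	1360000	2.0454
chr1	1360000	1370000	0.4438
chr1	1370000	1380000	2.5654
chr1	1380000	1390000	3.0248
chr1	1390000	1400000	0
chr1	1400000	1410000	0
chr1	1410000	1420000	0
chr1	1420000	1430000	0
chr1	1430000	1440000	25.0599
chr1	1440000	1450000	0.095
chr1	1450000	1460000	0
chr1	1460000	1470000	0.021
chr1	1470000	1480000	0
chr1	1480000	1490000	0
chr1	1490000	1500000	0.5177
chr1	1500000	1510000	0.7679
chr1	1510000	1520000	0
chr1	1520000	1530000	0
chr1	1530000	1540000	0.4793
chr1	1540000	1550000	1.5697
chr1	1550000	1560000	5.5868
chr1	1560000	1570000	0
chr1	1570000	1580000	0.0816
chr1	1580000	1590000	10.7107
chr1	1590000	1600000	0.281
chr1	1600000	1610000	3.0772
chr1	1610000	1620000	1.2281
chr1	1620000	1630000	0.629
chr1	1630000	1640000	0
chr1	1640000	1650000	0
chr1	1650000	1660000	0.0201
chr1	1660000	1670000	0.5573
chr1	1670000	1680000	0
chr1	1680000	1690000	7e-04
chr1	1690000	1700000	0
chr1	1700000	1710000	1.9178
chr1	1710000	1720000	0.8311
chr1	1720000	1730000	0
chr1	1730000	1740000	0
chr1	1740000	1750000	0.0126
chr1	1750000	1760000	5.0122
chr1	1760000	1770000	0.8111
chr1	1770000	1780000	2.8239
chr1	1780000	1790000	0
chr1	1790000	1800000	0
chr1	1800000	1810000	1.8693
chr1	1810000	1820000	0
chr1	1820000	1830000	0.7561
chr1	1830000	1840000	0
chr1	1840000	1850000	2.8849
chr1	1850000	1860000	0.0022
chr1	1860000	1870000	0
chr1	1870000	1880000	0.0376
chr1	1880000	1890000	0
chr1	1890000	1900000	0
chr1	1900000	1910000	3.4358
chr1	1910000	1920000	1.7397
chr1	1920000	1930000	0
chr1	1930000	1940000	0
chr1	1940000	1950000	8.8718
chr1	1950000	1960000	0
chr1	1960000	1970000	6.1638
chr1	1970000	1980000	0
chr1	1980000	1990000	1.0935
chr1	1990000	2e+06	0.5886
chr1	2e+06	2010000	0
chr1	2010000	2020000	0.0689
chr1	2020000	2030000	0
chr1	2030000	2040000	2.0922
chr1	2040000	2050000	0.6479
chr1	2050000	2060000	0
chr1	2060000	2070000	0
chr1	2070000	2080000	3.71
chr1	2080000	2090000	0
chr1	2090000	2100000	0
chr1	2100000	2110000	0
chr1	2110000	2120000	0
chr1	2120000	2130000	0.0012
chr1	2130000	2140000	2.9124
chr1	2140000	2150000	2.7612
chr1	2150000	2160000	0
chr1	2160000	2170000	0
chr1	2170000	2180000	0
chr1	2180000	2190000	0.236
chr1	2190000	2200000	0.0012
chr1	2200000	2210000	1.7691
chr1	2210000	2220000	0
chr1	2220000	2230000	1.2555
chr1	2230000	2240000	0
chr1	2240000	2250000	0
chr1	2250000	2260000	0
chr1	2260000	2270000	0
chr1	2270000	2280000	0.0047
chr1	2280000	2290000	0.5986
chr1	2290000	2300000	1.6512
chr1	2300000	2310000	0.0211
chr1	2310000	2320000	0
chr1	2320000	2330000	0
chr1	2330000	2340000	0
chr1	2340000	2350000	1.438
chr1	2350000	2360000	0
chr1	2360000	2370000	0.6456
chr1	2370000	2380000	0.4843
chr1	2380000	2390000	3.3921
chr1	2390000	2400000	0.2992
chr1	2400000	2410000	3.2364
chr1	2410000	2420000	2e-04
chr1	2420000	2430000	2.022
chr1	2430000	2440000	0
chr1	2440000	2450000	0
chr1	2450000	2460000	0.5969
chr1	2460000	2470000	0.6358
chr1	2470000	2480000	0
chr1	2480000	2490000	0
chr1	2490000	2500000	0
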