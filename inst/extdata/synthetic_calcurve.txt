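# SYNTHETIC radiocarbon calibration curve (for tests and examples only;
# NOT a published atmospheric curve). Columns: calendar age BP, 14C age BP,
# curve 1-sigma (years). Whitespace- or comma-separated.
0,25.0,12.0
50,80.0,12.0
100,134.8,12.1
150,189.5,12.2
200,243.8,12.3
250,297.6,12.5
300,350.9,12.6
350,403.6,12.9
400,455.5,13.1
450,506.6,13.4
500,556.9,13.7
550,606.4,14.0
600,654.8,14.3
650,702.4,14.6
700,749.0,15.0
750,794.7,15.3
800,839.6,15.6
850,883.5,15.9
900,926.7,16.2
950,969.1,16.5
1000,1010.9,16.8
1050,1052.1,17.1
1100,1092.9,17.3
1150,1133.3,17.5
1200,1173.5,17.7
1250,1213.5,17.8
1300,1253.5,17.9
1350,1293.6,18.0
1400,1334.0,18.0
1450,1374.6,18.0
1500,1415.7,17.9
1550,1457.3,17.9
1600,1499.6,17.7
1650,1542.6,17.6
1700,1586.3,17.4
1750,1630.9,17.2
1800,1676.3,17.0
1850,1722.7,16.7
1900,1770.0,16.4
1950,1818.3,16.1
2000,1867.5,15.8
2050,1917.5,15.5
2100,1968.5,15.1
2150,2020.2,14.8
2200,2072.7,14.5
2250,2125.8,14.1
2300,2179.5,13.8
2350,2233.7,13.5
2400,2288.2,13.3
2450,2343.0,13.0
2500,2398.0,12.8
2550,2453.0,12.6
2600,2507.9,12.4
2650,2562.6,12.2
2700,2617.0,12.1
2750,2671.0,12.0
2800,2724.4,12.0
2850,2777.3,12.0
2900,2829.4,12.0
2950,2880.7,12.1
3000,2931.3,12.2
3050,2980.9,12.4
3100,3029.7,12.5
3150,3077.5,12.7
3200,3124.4,13.0
3250,3170.3,13.2
3300,3215.4,13.5
3350,3259.5,13.8
3400,3302.9,14.1
3450,3345.5,14.4
3500,3387.5,14.8
3550,3428.8,15.1
3600,3469.7,15.4
3650,3510.2,15.8
3700,3550.4,16.1
3750,3590.5,16.4
3800,3630.5,16.7
3850,3670.6,16.9
3900,3710.8,17.2
3950,3751.4,17.4
4000,3792.4,17.6
4050,3833.8,17.7
4100,3875.9,17.9
4150,3918.7,17.9
4200,3962.2,18.0
4250,4006.6,18.0
4300,4051.8,18.0
4350,4097.9,17.9
4400,4145.0,17.8
4450,4193.0,17.7
4500,4241.9,17.5
4550,4291.8,17.3
4600,4342.5,17.1
4650,4394.0,16.8
4700,4446.3,16.6
4750,4499.2,16.3
4800,4552.8,16.0
4850,4606.9,15.6
4900,4661.3,15.3
4950,4716.1,15.0
5000,4771.0,14.7
5050,4826.0,14.3
5100,4881.0,14.0
5150,4935.7,13.7
5200,4990.2,13.4
5250,5044.3,13.1
5300,5097.9,12.9
5350,5150.9,12.7
5400,5203.2,12.5
5450,5254.8,12.3
5500,5305.6,12.2
5550,5355.4,12.1
5600,5404.4,12.0
5650,5452.5,12.0
5700,5499.6,12.0
5750,5545.8,12.1
5800,5591.1,12.2
5850,5635.5,12.3
5900,5679.1,12.4
5950,5721.9,12.6
6000,5764.0,12.8
6050,5805.5,13.1
6100,5846.5,13.4
6150,5887.1,13.6
6200,5927.4,13.9
6250,5967.5,14.3
6300,6007.5,14.6
6350,6047.5,14.9
6400,6087.7,15.3
6450,6128.2,15.6
6500,6169.0,15.9
6550,6210.4,16.2
6600,6252.3,16.5
6650,6294.9,16.8
6700,6338.2,17.0
6750,6382.3,17.3
6800,6427.3,17.5
6850,6473.2,17.7
6900,6520.0,17.8
6950,6567.8,17.9
7000,6616.5,18.0
7050,6666.1,18.0
7100,6716.5,18.0
7150,6767.9,18.0
7200,6819.9,17.9
7250,6872.7,17.8
7300,6926.1,17.6
7350,6980.1,17.4
7400,7034.5,17.2
7450,7089.1,17.0
7500,7144.0,16.7
7550,7199.0,16.4
7600,7254.0,16.1
7650,7308.8,15.8
7700,7363.4,15.5
7750,7417.6,15.2
7800,7471.3,14.8
7850,7524.5,14.5
7900,7577.0,14.2
7950,7628.8,13.9
8000,7679.8,13.6
8050,7729.9,13.3
8100,7779.1,13.0
8150,7827.4,12.8
8200,7874.8,12.6
8250,7921.2,12.4
8300,7966.8,12.2
8350,8011.4,12.1
8400,8055.2,12.1
8450,8098.2,12.0
8500,8140.5,12.0
8550,8182.2,12.0
8600,8223.3,12.1
8650,8264.0,12.2
8700,8304.3,12.3
8750,8344.5,12.5
8800,8384.5,12.7
8850,8424.5,12.9
8900,8464.6,13.2
8950,8505.0,13.5
9000,8545.8,13.8
9050,8587.0,14.1
9100,8628.7,14.4
9150,8671.1,14.7
9200,8714.2,15.1
9250,8758.1,15.4
9300,8802.9,15.7
9350,8848.5,16.0
9400,8895.1,16.4
9450,8942.6,16.6
9500,8991.1,16.9
9550,9040.4,17.2
9600,9090.7,17.4
9650,9141.8,17.6
9700,9193.7,17.7
9750,9246.3,17.8
9800,9299.5,17.9
9850,9353.3,18.0
9900,9407.6,18.0
9950,9462.2,18.0
10000,9517.1,17.9
10050,9572.0,17.8
10100,9627.0,17.7
10150,9681.9,17.5
10200,9736.5,17.3
10250,9790.9,17.1
10300,9844.7,16.9
10350,9898.1,16.6
10400,9950.8,16.3
10450,10002.7,16.0
10500,10053.9,15.7
10550,10104.3,15.4
10600,10153.8,15.0
10650,10202.3,14.7
10700,10249.9,14.4
10750,10296.6,14.0
10800,10342.4,13.7
10850,10387.2,13.4
10900,10431.3,13.2
10950,10474.5,12.9
11000,10517.0,12.7
11050,10558.8,12.5
11100,10600.0,12.3
11150,10640.8,12.2
11200,10681.3,12.1
11250,10721.4,12.0
11300,10761.5,12.0
11350,10801.5,12.0
11400,10841.6,12.1
11450,10881.9,12.1
11500,10922.5,12.3
11550,10963.6,12.4
11600,11005.2,12.6
11650,11047.4,12.8
11700,11090.3,13.1
11750,11134.0,13.3
11800,11178.5,13.6
11850,11223.9,13.9
11900,11270.3,14.2
11950,11317.5,14.6
12000,11365.7,14.9
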