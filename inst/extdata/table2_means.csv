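state,set,n,raw_mean,raw_sd,ind_mean,ind_sd,agg_mean,agg_sd,flag
11111,Both,229,97.5,6.3,1.0000,0.0000,0.9828,0.0474,
11123,Green,112,73.1,21.3,0.7404,0.2584,0.7461,0.2221,
12122,Green,112,68.0,20.7,0.6828,0.2359,0.6928,0.2157,
11313,Green,112,66.6,19.1,0.6794,0.2301,0.6781,0.1990,
13111,Blue,117,66.5,20.3,0.6716,0.2086,0.6774,0.2115,
21212,Green,112,64.3,19.3,0.6506,0.2314,0.6540,0.2010,
21122,Blue,117,63.8,16.5,0.6494,0.1707,0.6486,0.1715,
11223,Blue,117,61.4,22.5,0.6255,0.2317,0.6242,0.2343,
12113,Blue,117,58.9,21.7,0.6012,0.2236,0.5981,0.2264,
22121,Blue,117,58.7,18.3,0.5979,0.1858,0.5954,0.1901,
13311,Green,112,57.5,23.3,0.5799,0.2390,0.5834,0.2421,
11331,Blue,117,57.1,19.0,0.5784,0.1975,0.5786,0.1979,
21131,Green,112,56.4,19.8,0.5678,0.2181,0.5716,0.2058,
21312,Blue,117,56.0,18.2,0.5651,0.1877,0.5679,0.1891,
12232,Green,112,52.8,22.1,0.5284,0.2434,0.5340,0.2302,
13222,Blue,117,51.1,20.1,0.5179,0.2072,0.5163,0.2089,
22213,Green,112,49.3,17.4,0.4947,0.2090,0.4983,0.1820,
22321,Green,112,48.9,17.8,0.4898,0.2029,0.4939,0.1853,
13231,Green,112,48.1,23.6,0.4771,0.2446,0.4857,0.2457,
12332,Blue,117,46.6,19.3,0.4707,0.2017,0.4696,0.2008,
22231,Blue,117,43.9,18.1,0.4431,0.1859,0.4415,0.1888,
23322,Green,112,40.0,19.0,0.3940,0.2152,0.4010,0.1978,
31211,Blue,117,37.1,22.1,0.3717,0.2335,0.3709,0.2305,
23313,Blue,117,36.8,18.9,0.3686,0.2077,0.3678,0.1970,
32111,Green,112,33.1,20.5,0.3214,0.2406,0.3297,0.2134,
23133,Green,112,31.0,18.8,0.2969,0.2198,0.3069,0.1960,
32212,Blue,117,29.8,19.0,0.2960,0.2022,0.2953,0.1974,
31221,Green,112,29.7,18.8,0.2864,0.2291,0.2939,0.1956,
23233,Blue,117,28.1,17.7,0.2801,0.1841,0.2774,0.1846,
33112,Green,112,23.9,16.8,0.2254,0.2141,0.2337,0.1747,
31133,Blue,117,22.6,16.5,0.2193,0.1779,0.2196,0.1718,
33132,Blue,117,19.4,14.9,0.1855,0.1671,0.1796,0.1363,
33321,Blue,117,19.0,13.3,0.1831,0.1507,0.1824,0.1383,
31332,Green,112,18.7,13.1,0.1730,0.1746,0.4415,0.1888,transcription_error
32323,Blue,117,18.0,12.6,0.1728,0.1397,0.1718,0.1316,
33223,Green,112,16.3,13.3,0.1457,0.1801,0.1548,0.1387,
32333,Green,112,12.0,11.7,0.0986,0.1684,0.1091,0.1221,
33333,Both,229,7.0,9.1,0.0463,0.1136,0.0508,0.0888,
DEAD,Both,229,1.5,6.1,0.0000,0.0000,0.0107,0.0503,
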