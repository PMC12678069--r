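sex,ga_days,p10_g,p90_g
female,154,359,641
female,161,496.6,814.5
female,168,634.3,988
female,175,771.9,1161.5
female,182,909.5,1335
female,189,1047.1,1508.5
female,196,1184.7,1682
female,203,1322.3,1855.5
female,210,1459.9,2028.9
female,217,1597.6,2202.4
female,224,1735.2,2375.9
female,231,1872.8,2549.4
female,238,2010.4,2722.9
female,245,2148,2896.4
female,252,2285.6,3069.9
female,259,2423.2,3243.4
female,266,2560.9,3416.9
female,273,2698.5,3590.4
female,280,2836.1,3763.9
female,287,2888.1,3851.9
female,294,2940.2,3939.8
female,301,2992.3,4027.7
female,308,3044.3,4115.7
female,314,3088.9,4191.1
male,154,459,741
male,161,596.6,914.5
male,168,734.3,1088
male,175,871.9,1261.5
male,182,1009.5,1435
male,189,1147.1,1608.5
male,196,1284.7,1782
male,203,1422.3,1955.5
male,210,1559.9,2128.9
male,217,1697.6,2302.4
male,224,1835.2,2475.9
male,231,1972.8,2649.4
male,238,2110.4,2822.9
male,245,2248,2996.4
male,252,2385.6,3169.9
male,259,2523.2,3343.4
male,266,2660.9,3516.9
male,273,2798.5,3690.4
male,280,2936.1,3863.9
male,287,2988.1,3951.9
male,294,3040.2,4039.8
male,301,3092.3,4127.7
male,308,3144.3,4215.7
male,314,3188.9,4291.1
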