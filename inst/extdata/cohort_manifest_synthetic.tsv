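isolate_id	subject_id	trial	timepoint	genome_size	gc_percent	ani_vs_reference
T1_volA_d01_1	volA	1	d1	3162353	44.53	99.95
T1_volA_d01_2	volA	1	d1	3113588	44.59	99.99
T1_volA_d02_1	volA	1	d2	3173209	44.66	99.96
T1_volA_d02_2	volA	1	d2	3078618	44.57	99.98
T1_volA_d03_1	volA	1	d3	3176454	44.58	99.88
T1_volA_d03_2	volA	1	d3	3155221	44.55	99.97
T1_volA_d04_1	volA	1	d4	3178466	44.58	99.91
T1_volA_d04_2	volA	1	d4	3119509	44.57	99.97
T1_volA_d05_1	volA	1	d5	3108388	44.66	99.98
T1_volA_d05_2	volA	1	d5	3102008	44.58	99.89
T1_volA_d06_1	volA	1	d6	3165175	44.52	99.92
T1_volA_d06_2	volA	1	d6	3191023	44.56	99.9
T1_volA_d07_1	volA	1	d7	3147725	44.56	99.97
T1_volA_d07_2	volA	1	d7	3122416	44.61	99.93
T1_volA_d14_1	volA	1	d14	3136835	44.6	99.9
T1_volA_d14_2	volA	1	d14	3118135	44.61	99.98
T1_volB_d01_1	volB	1	d1	3152250	44.58	99.9
T1_volB_d01_2	volB	1	d1	3173770	44.6	99.92
T1_volB_d02_1	volB	1	d2	3147274	44.54	99.86
T1_volB_d02_2	volB	1	d2	3188902	44.59	99.98
T1_volB_d03_1	volB	1	d3	3175769	44.63	99.87
T1_volB_d03_2	volB	1	d3	3213678	44.62	99.87
T1_volB_d04_1	volB	1	d4	3105285	44.57	99.92
T1_volB_d04_2	volB	1	d4	3196022	44.67	99.94
T1_volB_d05_1	volB	1	d5	3156551	44.57	99.9
T1_volB_d05_2	volB	1	d5	3164127	44.6	99.92
T1_volB_d06_1	volB	1	d6	3115016	44.64	99.88
T1_volB_d06_2	volB	1	d6	3145789	44.58	99.91
T1_volB_d07_1	volB	1	d7	3121850	44.65	99.87
T1_volB_d07_2	volB	1	d7	3161581	44.62	99.9
T1_volB_d14_1	volB	1	d14	3195269	44.63	99.97
T1_volB_d14_2	volB	1	d14	3145342	44.62	99.96
T1_volC_d01_1	volC	1	d1	2230620	41.93	70.92
T1_volC_d01_2	volC	1	d1	2177089	42.09	69.57
T1_volC_d02_1	volC	1	d2	2182349	42.13	69.34
T1_volC_d02_2	volC	1	d2	2235016	41.91	69.57
T1_volC_d03_1	volC	1	d3	2169637	42.17	69.44
T1_volC_d03_2	volC	1	d3	2173159	41.85	69.44
T1_volC_d04_1	volC	1	d4	2258951	42.1	69.54
T1_volC_d04_2	volC	1	d4	2193722	42.24	69.52
T1_volC_d05_1	volC	1	d5	2223214	42.16	69.91
T1_volC_d05_2	volC	1	d5	2262575	42.03	69.76
T1_volC_d06_1	volC	1	d6	2236418	41.99	71.25
T1_volC_d06_2	volC	1	d6	2123760	41.82	71.36
T1_volC_d07_1	volC	1	d7	2114733	42.15	70.43
T1_volC_d07_2	volC	1	d7	2186089	42.11	69.52
T1_volC_d14_1	volC	1	d14	2206601	42.05	70.65
T1_volC_d14_2	volC	1	d14	2203035	42.19	69.75
T2_rat1_d01_1	rat1	2	d1	3153777	44.58	99.97
T2_rat1_d01_2	rat1	2	d1	3118450	44.51	99.91
T2_rat2_d01_1	rat2	2	d1	3171595	44.57	99.9
T2_rat2_d01_2	rat2	2	d1	3203317	44.61	99.94
T2_rat3_d01_1	rat3	2	d1	3127161	44.6	99.96
T2_rat3_d01_2	rat3	2	d1	3163625	44.62	99.88
T2_rat1_d02_1	rat1	2	d2	3145450	44.59	99.97
T2_rat1_d02_2	rat1	2	d2	3162465	44.61	99.94
T2_rat2_d02_1	rat2	2	d2	3154305	44.61	99.87
T2_rat2_d02_2	rat2	2	d2	3196443	44.56	99.86
T2_rat3_d02_1	rat3	2	d2	3139271	44.56	99.92
T2_rat3_d02_2	rat3	2	d2	3157753	44.6	99.92
T2_rat1_d03_1	rat1	2	d3	3157360	44.6	99.92
T2_rat1_d03_2	rat1	2	d3	3169127	44.52	99.88
T2_rat2_d03_1	rat2	2	d3	3118400	44.6	99.87
T2_rat2_d03_2	rat2	2	d3	3140721	44.58	99.9
T2_rat3_d03_1	rat3	2	d3	3114962	44.64	99.9
T2_rat3_d03_2	rat3	2	d3	3174941	44.61	99.97
T2_rat1_d04_1	rat1	2	d4	3121978	44.55	99.97
T2_rat2_d04_1	rat2	2	d4	3142014	44.6	99.94
T2_rat2_d04_2	rat2	2	d4	3209906	44.55	99.98
T2_rat3_d04_1	rat3	2	d4	3167649	44.62	99.87
T2_rat3_d04_2	rat3	2	d4	3102184	44.63	99.96
T2_rat1_d05_1	rat1	2	d5	3143657	44.63	99.91
T2_rat1_d05_2	rat1	2	d5	3139346	44.61	99.91
T2_rat2_d05_1	rat2	2	d5	3154632	44.59	99.88
T2_rat2_d05_2	rat2	2	d5	3163494	44.64	99.87
T2_rat3_d05_1	rat3	2	d5	3146523	44.6	99.98
T2_rat3_d05_2	rat3	2	d5	3123282	44.52	99.85
T2_rat1_d06_1	rat1	2	d6	3164514	44.66	99.95
T2_rat1_d06_2	rat1	2	d6	3118104	44.62	99.85
T2_rat2_d06_1	rat2	2	d6	3166743	44.63	99.92
T2_rat2_d06_2	rat2	2	d6	3215565	44.58	99.94
T2_rat3_d06_1	rat3	2	d6	3127773	44.57	99.9
T2_rat3_d06_2	rat3	2	d6	3142979	44.56	99.93
T2_rat1_d07_1	rat1	2	d7	3114306	44.62	99.98
T2_rat1_d07_2	rat1	2	d7	3152105	44.62	99.97
T2_rat2_d07_1	rat2	2	d7	3118825	44.51	99.9
T2_rat2_d07_2	rat2	2	d7	3195117	44.55	99.92
T2_rat1_d14_1	rat1	2	d14	3177621	44.6	99.9
T2_rat1_d14_2	rat1	2	d14	3194256	44.58	99.99
T2_rat2_d14_1	rat2	2	d14	3207250	44.61	99.93
T2_rat2_d14_2	rat2	2	d14	3139987	44.6	99.98
T2_rat3_d14_1	rat3	2	d14	3141861	44.6	99.88
T2_rat3_d14_2	rat3	2	d14	3146851	44.57	99.87
T3_Y01_w02	Y01	3	w2	3135398	44.57	99.86
T3_Y02_w02	Y02	3	w2	3091716	44.53	99.99
T3_Y03_w02	Y03	3	w2	3171883	44.58	99.93
T3_M01_w04	M01	3	w4	3163649	44.59	99.9
T3_M02_w04	M02	3	w4	3194995	44.56	99.9
T3_M03_w04	M03	3	w4	3130805	44.61	99.9
T3_E01_w06	E01	3	w6	3178420	44.62	99.95
T3_E02_w06	E02	3	w6	3208428	44.59	99.87
T3_E03_w08	E03	3	w8	3132982	44.65	99.91
T3_Y04_w08	Y04	3	w8	3187393	44.64	99.88
T3_M04_w13	M04	3	w13	3166393	44.56	99.86
T3_E04_w13	E04	3	w13	3150448	44.57	99.99
T3_Y05_w17	Y05	3	w17	3143640	44.62	99.96
T3_M05_w17	M05	3	w17	3122069	44.58	99.96
T3_E05_w17	E05	3	w17	3182893	44.57	99.9
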