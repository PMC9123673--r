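chrom	mb	n_snps	lr_m	lr_f	du_m	du_f	lw_m	lw_f	pi_m	pi_f	sy_m	sy_f
1	274.3	4858	145.2	122.9	156.8	128.1	158.9	142.0	145.8	129.9	159.3	134.8
2	151.9	3306	109.5	129.9	108.8	131.3	117.8	149.0	107.9	129.5	115.8	138.5
3	132.9	2912	111.6	133.5	112.2	131.5	121.0	154.7	113.4	130.4	120.4	140.2
4	130.9	3002	104.2	132.0	102.6	133.4	110.2	151.5	103.3	135.9	108.7	140.4
5	104.5	2290	98.1	140.8	98.4	136.0	103.6	156.8	96.8	144.2	105.1	148.5
6	170.8	3440	119.6	149.3	125.9	156.8	130.3	179.4	120.8	149.8	127.7	162.5
7	121.8	2751	113.4	137.2	112.3	137.8	117.6	158.6	107.8	140.0	115.6	146.6
8	139.0	2924	102.1	122.2	103.1	124.3	105.4	137.6	104.0	126.8	106.3	132.6
9	139.5	3168	104.7	142.0	103.6	143.5	107.3	163.7	104.7	147.8	108.8	156.5
10	69.4	1510	93.9	121.3	91.8	124.3	98.0	138.3	88.3	131.3	94.7	131.4
11	79.2	1846	69.7	114.4	67.8	110.0	79.3	122.6	63.9	120.6	78.3	117.8
12	61.6	1296	78.3	122.0	77.3	118.0	86.5	133.7	71.3	123.6	82.4	127.2
13	208.3	3669	116.9	109.5	126.0	116.9	127.5	123.4	117.6	115.5	126.1	117.6
14	141.8	3284	105.3	124.7	109.8	126.8	114.8	151.9	105.8	124.4	112.7	137.0
15	140.7	2916	98.9	113.0	101.7	115.6	104.9	124.8	99.8	116.4	106.0	119.8
16	79.9	1829	67.0	105.5	69.9	103.6	77.0	111.3	63.2	110.5	74.4	108.4
17	63.5	1399	61.4	106.0	71.9	106.3	69.6	115.7	60.5	106.4	69.3	113.2
18	56.0	1257	54.5	89.5	54.6	87.4	57.6	100.3	56.1	94.7	59.4	95.6
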