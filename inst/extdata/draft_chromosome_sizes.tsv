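chromosome	contigs	bases
1	26557	181826552
2	14384	106718223
3	12649	91132767
4	9170	68844569
5	7553	56965239
6	6534	48705183
7	4755	35338084
8	4751	35279744
9	2286	18014631
10	3733	28668829
11	2720	22659912
12	2372	18944919
13	2354	18696996
14	2367	19181786
15	2265	16791072
16	1967	14411805
17	1635	12015459
18	51	139801
19	1399	9478246
20	1424	9943105
21	1328	9405728
22	1865	13252797
23	937	6420024
24	569	3613335
25	834	4963017
26	1040	5925429
27	161	687724
28	717	4244239
29	803	3649262
30	693	3524564
W	50	108225
Z	24970	47735835
Un	7748	18627908
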