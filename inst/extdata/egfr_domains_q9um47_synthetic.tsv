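domain_index	start_aa	end_aa
1	40	78
2	79	117
3	118	157
4	158	196
5	197	235
6	236	274
7	275	314
8	315	353
9	354	392
10	393	431
11	432	471
12	472	510
13	511	549
14	550	588
15	589	628
16	629	667
17	668	706
18	707	745
19	746	784
20	785	824
21	825	863
22	864	902
23	903	941
24	942	981
25	982	1020
26	1021	1059
27	1060	1098
28	1099	1138
29	1139	1177
30	1178	1216
31	1217	1255
32	1256	1295
33	1296	1334
34	1335	1373
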