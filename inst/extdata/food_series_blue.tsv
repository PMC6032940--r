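# food_series colour=blue rho=-0.822973
step	rods
1	2
2	8
3	2
4	8
5	8
6	2
7	8
8	8
9	2
10	8
11	2
12	8
13	2
14	8
15	8
16	2
17	8
18	2
19	8
20	2
21	8
22	2
23	8
24	2
25	8
26	2
27	8
28	2
29	8
30	2
31	8
32	2
33	8
34	2
35	8
36	2
37	8
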