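# food_series colour=red rho=0.650556
step	rods
1	8
2	8
3	8
4	8
5	8
6	8
7	8
8	8
9	8
10	8
11	2
12	8
13	8
14	8
15	8
16	8
17	8
18	2
19	8
20	2
21	2
22	2
23	2
24	2
25	2
26	2
27	2
28	2
29	2
30	2
31	2
32	2
33	2
34	2
35	8
36	8
37	8
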