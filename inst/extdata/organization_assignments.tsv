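number	organization
1	B
2	B
3	A
4	A
5	A
6	A
7	A
8	A
9	A
10	A
11	A
12	A
13	A
14	A
15	A
16	A
17	A
18	A
19	A
20	A
21	A
22	A
23	A
24	A
25	A
26	A
27	A
28	A
29	A
30	A
31	A
32	A
33	A
34	A
35	A
36	A
37	A
38	C
39	B
40	A
41	B
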