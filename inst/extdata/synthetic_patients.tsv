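patient_id	entry_day	duration_days	event
1	1.3	9259.5	1
2	6	2367.9	1
3	6.5	5303.9	0
4	17.7	22641.8	1
5	18.9	1605	1
6	27.5	7538.9	0
7	67.2	2850.6	1
8	153.4	3394.5	1
9	153.5	3783.2	1
10	168.4	25478.4	1
11	192	1095.9	1
12	203.1	2481.9	1
13	230.5	10148.2	1
14	253.1	18924.6	1
15	254.7	2049.3	1
16	276.5	8567.2	1
17	312.9	2064.7	1
18	348	1014.8	1
19	374	205.9	0
20	376.1	657.3	1
21	390.7	8335.5	0
22	449.7	673.4	1
23	451.6	4428.9	1
24	466.3	622.5	1
25	489.3	306.9	0
26	510.5	1101.9	1
27	522.5	3663.9	0
28	597	6557.8	1
29	608.1	8393.4	1
30	609.4	8322.2	1
31	636	4527.1	1
32	641.8	9048.7	1
33	658.9	2595.9	1
34	757.6	9310.1	1
35	765	16792.7	1
36	800.7	5532.2	0
37	826.5	14416.3	1
38	929.1	2726.5	1
39	942.8	1682.1	1
40	997.6	5748.1	1
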