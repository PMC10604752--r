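parent	child	associated	branch_only	n_patients	pct_patients
1	3	045,729,722,721,359,353,438,427,344,300,728,138,357	045,359,438,427,344,138	31	37.35
1	4	290	290	8	9.64
1	9	721,729,722,436		1	1.20
1	2	335		10	12.05
3	11	332,729,722,721,352,813,353,344,300,728,311	352,813,332,311	3	3.61
3	7	729,356,438,427,300,434,436		5	6.02
3	8	343,045,138	343	6	7.23
3	5	434,351,438	351	9	10.84
3	10	722,359,353,427,300,185	185	3	3.61
3	6	335,721,356,355,300,323,349,357	349,355,323	4	4.82
11	17	332,718,300,290,813	290,718	1	1.20
11	14	729,722,721,353,344,355,300,728,311	355	1	1.20
11	16	352		1	1.20
7	12	434,356,436,438		3	3.61
7	13	335,332,729,359,438,427,300	332	2	2.41
0	1	335,729,722,721,353,300,728,357,436	335,729,722,721,353,300,728,357,436	55	66.27
17	22	332,718,300,290,813		1	1.20
22	24	332,718,300,290,813		1	1.20
14	20	729,722,721,353,344,355,300,728,311		1	1.20
16	21	352		1	1.20
10	18	729,722,359,353,427,300,185		3	3.61
21	23	352		1	1.20
6	15	335,721,356,355,300,323,349,357		4	4.82
13	19	335,332,729,359,438,427,300,434		2	2.41
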