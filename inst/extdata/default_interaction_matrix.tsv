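type	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y	SOL
A	-39	-44	2	2	-47	-22	0	-60	5	-55	-40	2	-13	2	10	-19	-20	-58	-18	-15	4
C	-44	-50	1	1	-53	-25	-1	-68	5	-62	-45	1	-15	1	10	-22	-23	-65	-21	-18	6
D	2	1	59	59	1	5	-17	-1	-41	0	2	9	6	9	-40	5	5	-1	6	6	-8
E	2	1	59	59	1	5	-17	-1	-41	0	2	9	6	9	-40	5	5	-1	6	6	-8
F	-47	-53	1	1	-56	-27	-2	-71	5	-65	-48	1	-16	1	10	-23	-24	-68	-22	-19	6
G	-22	-25	5	5	-27	-11	3	-36	7	-32	-22	5	-5	5	10	-9	-9	-34	-8	-6	-1
H	0	-1	-17	-17	-2	3	20	-4	34	-3	0	8	5	8	35	4	4	-4	4	5	-7
I	-60	-68	-1	-1	-71	-36	-4	-90	3	-82	-61	-1	-22	-1	10	-31	-32	-87	-30	-26	10
K	5	5	-41	-41	5	7	34	3	60	4	5	9	8	9	60	7	7	4	7	8	-9
L	-55	-62	0	0	-65	-32	-3	-82	4	-75	-56	0	-20	0	10	-28	-29	-79	-27	-23	8
M	-40	-45	2	2	-48	-22	0	-61	5	-56	-41	2	-13	2	10	-19	-20	-59	-18	-15	4
N	2	1	9	9	1	5	8	-1	9	0	2	9	6	9	10	5	5	-1	6	6	-8
P	-13	-15	6	6	-16	-5	5	-22	8	-20	-13	6	0	6	10	-3	-4	-21	-3	-1	-4
Q	2	1	9	9	1	5	8	-1	9	0	2	9	6	9	10	5	5	-1	6	6	-8
R	10	10	-40	-40	10	10	35	10	60	10	10	10	10	10	60	10	10	10	10	10	-10
S	-19	-22	5	5	-23	-9	4	-31	7	-28	-19	5	-3	5	10	-7	-7	-30	-6	-5	-2
T	-20	-23	5	5	-24	-9	4	-32	7	-29	-20	5	-4	5	10	-7	-8	-31	-7	-5	-2
V	-58	-65	-1	-1	-68	-34	-4	-87	4	-79	-59	-1	-21	-1	10	-30	-31	-83	-29	-24	9
W	-18	-21	6	6	-22	-8	4	-30	7	-27	-18	6	-3	6	10	-6	-7	-29	-6	-4	-2
Y	-15	-18	6	6	-19	-6	5	-26	8	-23	-15	6	-1	6	10	-5	-5	-24	-4	-3	-3
SOL	4	6	-8	-8	6	-1	-7	10	-9	8	4	-8	-4	-8	-10	-2	-2	9	-2	-3	0
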