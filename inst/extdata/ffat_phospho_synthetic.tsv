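residue	U1	U2	U3	U4	U5	U6	C1	C2	C3	C4	C5	C6	C7	D1	D2	D3	D4	D5	D6
A	1	1	1	1	1	1	2	4.5	4.5	3.5	0	0	2	1	1	1	1	1	1
C	1.5	1.5	1.5	1.5	1.5	1.5	2.5	4.5	4.5	3	0.5	0.5	3	1	1	1	1	1	1
D	0	0	0	0	0	0	0	4.5	4.5	2.5	3.5	0	0.5	0	0	0	0	0	0
E	0	0	0	0	0	0	0	4.5	4.5	2.5	3.5	0	0	0	0	0	0	0	0
F	1.5	1.5	1.5	1.5	1.5	1.5	3.5	0	0	4	3.5	0.5	3	1	1	1	1	1	1
G	1	1	1	1	1	1	2	4.5	4.5	3.5	1.5	0	2	1	1	1	1	1	1
H	1.5	1.5	1.5	1.5	1.5	1.5	2.5	4.5	4.5	4	3.5	0.5	3	1	1	1	1	1	1
I	1.5	1.5	1.5	1.5	1.5	1.5	3	3	3	4	3.5	0.5	3	1	1	1	1	1	1
K	2	2	2	2	2	2	4	4.5	4.5	4	3.5	0.5	3.5	1.5	1.5	1.5	1.5	1.5	1.5
L	1.5	1.5	1.5	1.5	1.5	1.5	3	2.5	2.5	4	3.5	0.5	3	1	1	1	1	1	1
M	1.5	1.5	1.5	1.5	1.5	1.5	3	2.5	2.5	4	3.5	0.5	3	1	1	1	1	1	1
N	1	1	1	1	1	1	1.5	4.5	4.5	3	3.5	0	1.5	1	1	1	1	1	1
P	1.5	1.5	1.5	1.5	1.5	1.5	4	4.5	4.5	4	4	2	3.5	1	1	1	1	1	1
Q	1	1	1	1	1	1	1.5	4.5	4.5	4	3.5	0	1.5	1	1	1	1	1	1
R	2	2	2	2	2	2	4	4.5	4.5	4	3.5	0.5	3.5	1.5	1.5	1.5	1.5	1.5	1.5
S	0.5	0.5	0.5	0.5	0.5	0.5	1	4.5	4.5	0	1	0	1	0.5	0.5	0.5	0.5	0.5	0.5
T	0.5	0.5	0.5	0.5	0.5	0.5	1	4.5	4.5	0	2	0	1	0.5	0.5	0.5	0.5	0.5	0.5
V	1.5	1.5	1.5	1.5	1.5	1.5	3	3	3	4	2.5	0.5	3	1	1	1	1	1	1
W	1.5	1.5	1.5	1.5	1.5	1.5	4	1.5	1.5	4	4	2	3.5	1	1	1	1	1	1
Y	1.5	1.5	1.5	1.5	1.5	1.5	3.5	0.5	0	4	3.5	0.5	3	1	1	1	1	1	1
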