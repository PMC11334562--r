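residue	rigidity	flexibility	irreplaceability
A	0.6	0.357	0.3
C	0.68	0.346	0.95
D	0.46	0.511	0.44
E	0.5	0.497	0.42
F	0.88	0.314	0.72
G	0.3	0.544	0.9
H	0.65	0.323	0.68
I	0.8	0.462	0.48
K	0.44	0.466	0.36
L	0.75	0.365	0.5
M	0.7	0.295	0.6
N	0.48	0.463	0.38
P	0.95	0.509	0.85
Q	0.52	0.493	0.4
R	0.55	0.529	0.55
S	0.42	0.507	0.32
T	0.58	0.444	0.34
V	0.78	0.386	0.46
W	0.9	0.305	1
Y	0.85	0.42	0.7
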