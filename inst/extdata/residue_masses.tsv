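code	chirality	mono_mass	avg_mass	polarity_class
G	achiral	57.02146	57.0519	hydrophobic-aliphatic
A	L	71.03711	71.0788	hydrophobic-aliphatic
a	D	71.03711	71.0788	hydrophobic-aliphatic
S	L	87.03203	87.0782	hydrophilic-uncharged
s	D	87.03203	87.0782	hydrophilic-uncharged
P	L	97.05276	97.1167	hydrophobic-aliphatic
p	D	97.05276	97.1167	hydrophobic-aliphatic
V	L	99.06841	99.1326	hydrophobic-aliphatic
v	D	99.06841	99.1326	hydrophobic-aliphatic
T	L	101.04768	101.1051	hydrophilic-uncharged
t	D	101.04768	101.1051	hydrophilic-uncharged
C	L	103.00919	103.1388	hydrophilic-uncharged
c	D	103.00919	103.1388	hydrophilic-uncharged
L	L	113.08406	113.1594	hydrophobic-aliphatic
l	D	113.08406	113.1594	hydrophobic-aliphatic
I	L	113.08406	113.1594	hydrophobic-aliphatic
i	D	113.08406	113.1594	hydrophobic-aliphatic
N	L	114.04293	114.1038	hydrophilic-uncharged
n	D	114.04293	114.1038	hydrophilic-uncharged
D	L	115.02694	115.0886	hydrophilic-negative
d	D	115.02694	115.0886	hydrophilic-negative
Q	L	128.05858	128.1307	hydrophilic-uncharged
q	D	128.05858	128.1307	hydrophilic-uncharged
K	L	128.09496	128.1741	hydrophilic-positive
k	D	128.09496	128.1741	hydrophilic-positive
E	L	129.04259	129.1155	hydrophilic-negative
e	D	129.04259	129.1155	hydrophilic-negative
M	L	131.04049	131.1926	hydrophobic-aliphatic
m	D	131.04049	131.1926	hydrophobic-aliphatic
H	L	137.05891	137.1411	hydrophilic-positive
h	D	137.05891	137.1411	hydrophilic-positive
F	L	147.06841	147.1766	hydrophobic-aromatic
f	D	147.06841	147.1766	hydrophobic-aromatic
R	L	156.10111	156.1875	hydrophilic-positive
r	D	156.10111	156.1875	hydrophilic-positive
Y	L	163.06333	163.176	hydrophobic-aromatic
y	D	163.06333	163.176	hydrophobic-aromatic
W	L	186.07931	186.2132	hydrophobic-aromatic
w	D	186.07931	186.2132	hydrophobic-aromatic
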