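resid	max_asa
ALA	106
ARG	248
ASN	157
ASP	163
CYS	135
GLN	198
GLU	194
GLY	84
HIS	184
ILE	169
LEU	164
LYS	205
MET	188
PHE	197
PRO	136
SER	130
THR	142
TRP	227
TYR	222
VAL	142
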