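REMARK ISOPEPTIDE id=syn_cnaa_aspglu_1 topology=CnaA-like triad_type=Lys-Asp-Glu flank=EFPNMTNSQCHLEMAVCPDLDQVKYCCPWKCIIVKAFDGANIN
ATOM      1  CB  LYS T   1       7.432   2.405  -3.256  1.00  0.00           C
ATOM      2  CG  LYS T   1       5.932   2.646  -3.302  1.00  0.00           C
ATOM      3  CD  LYS T   1       5.233   1.950  -2.145  1.00  0.00           C
ATOM      4  CE  LYS T   1       3.733   2.192  -2.191  1.00  0.00           C
ATOM      5  NZ  LYS T   1       3.057   1.519  -1.072  1.00  0.00           N
ATOM      6  CD  GLU T   2       4.877   1.085   2.016  1.00  0.00           C
ATOM      7  OE1 GLU T   2       5.167   1.602   0.915  1.00  0.00           O
ATOM      8  OE2 GLU T   2       5.628   1.008   3.012  1.00  0.00           O
ATOM      9  CG  GLU T   2       3.489   0.488   2.180  1.00  0.00           C
ATOM     10  CB  GLU T   2       3.282  -0.101   3.566  1.00  0.00           C
ATOM     11  CB  ASP T   3       1.530   0.000   0.000  1.00  0.00           C
ATOM     12  CG  ASP T   3       2.124   0.591  -1.268  1.00  0.00           C
ATOM     13  OD1 ASP T   3       2.703  -0.120  -2.088  1.00  0.00           O
ATOM     14  OD2 ASP T   3       1.303   1.210  -2.112  1.00  0.00           O
END
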