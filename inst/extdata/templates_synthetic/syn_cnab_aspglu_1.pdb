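REMARK ISOPEPTIDE id=syn_cnab_aspglu_1 topology=CnaB-like triad_type=Lys-Asp-Glu flank=FALWDDILGDFECYSLKMKVVKHFDNLDDHPFTPGDKEHGCNR
ATOM      1  CB  LYS T   1       2.951  -4.541   0.142  1.00  0.00           C
ATOM      2  CG  LYS T   1       3.809  -3.289   0.059  1.00  0.00           C
ATOM      3  CD  LYS T   1       3.117  -2.207  -0.753  1.00  0.00           C
ATOM      4  CE  LYS T   1       3.974  -0.955  -0.837  1.00  0.00           C
ATOM      5  NZ  LYS T   1       3.304   0.091  -1.622  1.00  0.00           N
ATOM      6  CD  GLU T   2       5.354   2.430  -3.457  1.00  0.00           C
ATOM      7  OE1 GLU T   2       5.617   1.457  -2.718  1.00  0.00           O
ATOM      8  OE2 GLU T   2       6.188   3.160  -4.034  1.00  0.00           O
ATOM      9  CG  GLU T   2       3.892   2.776  -3.689  1.00  0.00           C
ATOM     10  CB  GLU T   2       3.730   3.978  -4.605  1.00  0.00           C
ATOM     11  CB  ASP T   3       1.530   0.000   0.000  1.00  0.00           C
ATOM     12  CG  ASP T   3       2.124   0.591  -1.268  1.00  0.00           C
ATOM     13  OD1 ASP T   3       1.531   0.511  -2.343  1.00  0.00           O
ATOM     14  OD2 ASP T   3       2.368   1.899  -1.293  1.00  0.00           O
END
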