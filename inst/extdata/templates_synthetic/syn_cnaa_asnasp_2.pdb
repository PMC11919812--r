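REMARK ISOPEPTIDE id=syn_cnaa_asnasp_2 topology=CnaA-like triad_type=Lys-Asn-Asp flank=NINPVARRGNHHDNDNYVRTKVQAYRPINSSRYSVDGCMTKKR
ATOM      1  CB  LYS T   1       7.112   2.758  -3.557  1.00  0.00           C
ATOM      2  CG  LYS T   1       5.610   2.963  -3.455  1.00  0.00           C
ATOM      3  CD  LYS T   1       5.029   2.168  -2.298  1.00  0.00           C
ATOM      4  CE  LYS T   1       3.526   2.373  -2.196  1.00  0.00           C
ATOM      5  NZ  LYS T   1       2.964   1.604  -1.076  1.00  0.00           N
ATOM      6  CG  ASP T   2       4.932   1.277   1.933  1.00  0.00           C
ATOM      7  OD1 ASP T   2       5.127   1.851   0.840  1.00  0.00           O
ATOM      8  OD2 ASP T   2       5.724   1.251   2.900  1.00  0.00           O
ATOM      9  CB  ASP T   2       3.619   0.536   2.126  1.00  0.00           C
ATOM     10  CB  ASN T   3       1.530   0.000   0.000  1.00  0.00           C
ATOM     11  CG  ASN T   3       2.124   0.591  -1.268  1.00  0.00           C
ATOM     12  OD1 ASN T   3       2.797  -0.097  -2.033  1.00  0.00           O
ATOM     13  ND2 ASN T   3       1.290   1.102  -2.169  1.00  0.00           N
END
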