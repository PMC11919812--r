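REMARK ISOPEPTIDE id=syn_cnab_asnglu_2 topology=CnaB-like triad_type=Lys-Asn-Glu flank=SAFTKNHIPMYFEQKMWGILADPIGQSNSAHITHHNWMNYVSK
ATOM      1  CB  LYS T   1       3.334  -4.626  -0.303  1.00  0.00           C
ATOM      2  CG  LYS T   1       4.032  -3.286  -0.135  1.00  0.00           C
ATOM      3  CD  LYS T   1       3.334  -2.203  -0.942  1.00  0.00           C
ATOM      4  CE  LYS T   1       4.032  -0.863  -0.774  1.00  0.00           C
ATOM      5  NZ  LYS T   1       3.357   0.184  -1.554  1.00  0.00           N
ATOM      6  CD  GLU T   2       5.384   2.741  -3.100  1.00  0.00           C
ATOM      7  OE1 GLU T   2       5.652   1.745  -2.394  1.00  0.00           O
ATOM      8  OE2 GLU T   2       6.211   3.552  -3.571  1.00  0.00           O
ATOM      9  CG  GLU T   2       3.925   3.012  -3.427  1.00  0.00           C
ATOM     10  CB  GLU T   2       3.755   4.252  -4.289  1.00  0.00           C
ATOM     11  CB  ASN T   3       1.530   0.000   0.000  1.00  0.00           C
ATOM     12  CG  ASN T   3       2.124   0.591  -1.268  1.00  0.00           C
ATOM     13  OD1 ASN T   3       1.586   0.417  -2.361  1.00  0.00           O
ATOM     14  ND2 ASN T   3       2.255   1.913  -1.339  1.00  0.00           N
END
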