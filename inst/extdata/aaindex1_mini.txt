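H KLEP840101
D Net charge (Klein et al., 1984)
R LIT:1008055 PMID:6547351
A Klein, P., Kanehisa, M. and DeLisi, C.
T Prediction of protein function from sequence properties:
  Discriminant analysis of a data base
J Biochim. Biophys. Acta 787, 221-226 (1984)
C ZIMJ680104    0.941
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      0.      1.      0.     -1.      0.      0.     -1.      0.      0.      0.
      0.      1.      0.      0.      0.      0.      0.      0.      0.      0.
//
H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982)
R LIT:0807099 PMID:7108955
A Kyte, J. and Doolittle, R.F.
T A simple method for displaying the hydropathic character of a protein
J J. Mol. Biol. 157, 105-132 (1982)
C CHOC760103    0.964
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5
     3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7    -0.9    -1.3     4.2
//
H SYNIC000101
D Synthetic incomplete test scale (one missing residue)
R
A none
T synthetic fixture entry, not part of the AAindex release
J none
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.0     0.5      NA     0.2     0.8     0.1     0.3     0.4     0.6     0.9
     0.7     0.5     0.2     0.1     0.3     0.2     0.4     0.8     0.6     1.0
//
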