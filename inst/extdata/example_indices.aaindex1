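H FXTS0101
D Synthetic fixture scale 1 (rank permutation, tie-free)
R none
A dcgr fixture
T Hand-written synthetic scale for testing
J none
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.00    5.00    9.00   13.00   17.00    2.00    6.00   10.00   14.00   18.00
    3.00    7.00   11.00   15.00   19.00    4.00    8.00   12.00   16.00   20.00
//
H FXTS0102
D Synthetic fixture scale 2 (descending decimals, tie-free)
R none
A dcgr fixture
T Hand-written synthetic scale for testing
J none
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    9.81    8.72    7.63    6.54    5.45    4.36    3.27    2.18    1.09    0.91
   -0.11   -1.22   -2.33   -3.44   -4.55   -5.66   -6.77   -7.88   -8.99   -9.10
//
H FXTS0103
D Synthetic fixture scale 3 (primes, tie-free)
R none
A dcgr fixture
T Hand-written synthetic scale for testing
J none
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    2.00    3.00    5.00    7.00   11.00   13.00   17.00   19.00   23.00   29.00
   31.00   37.00   41.00   43.00   47.00   53.00   59.00   61.00   67.00   71.00
//
H FXTS0104
D Synthetic fixture scale 4 (alternating signs, tie-free)
R none
A dcgr fixture
T Hand-written synthetic scale for testing
J none
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.10   -0.20    0.30   -0.40    0.50   -0.60    0.70   -0.80    0.90   -1.00
    1.10   -1.20    1.30   -1.40    1.50   -1.60    1.70   -1.80    1.90   -2.00
//
H FXTS0105
D Synthetic fixture scale 5 (powers of 1.3, tie-free)
R none
A dcgr fixture
T Hand-written synthetic scale for testing
J none
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.30    1.69    2.20    2.86    3.71    4.83    6.27    8.16   10.60   13.79
   17.92   23.30   30.29   39.37   51.19   66.54   86.50  112.46  146.19  190.05
//
H FXTS0106
D Synthetic fixture scale 6 (shuffled tenths, tie-free)
R none
A dcgr fixture
T Hand-written synthetic scale for testing
J none
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.70    1.40    0.20    1.90    0.90    1.10    0.40    1.70    0.60    1.30
    0.10    1.60    0.80    2.00    0.30    1.20    0.50    1.80    1.00    1.50
//
H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982); contains tied values
R PMID:7108955
A Kyte J. and Doolittle R.F.
T A simple method for displaying the hydropathic character of a protein
J J. Mol. Biol. 157, 105-132 (1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5
     3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7    -0.9    -1.3     4.2
//
H FXTS0901
D Synthetic fixture scale with a missing value (incomplete)
R none
A dcgr fixture
T Hand-written synthetic scale for testing
J none
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.00    2.00    3.00    4.00      NA    6.00    7.00    8.00    9.00   10.00
   11.00   12.00   13.00   14.00   15.00   16.00   17.00   18.00   19.00   20.00
//
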