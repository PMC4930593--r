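MOTIF MYC
A C G T
3.33333333333333 90.00000000000000 3.33333333333333 3.33333333333333
85 5 5 5
2.66666666666667 92.00000000000000 2.66666666666667 2.66666666666667
4 4 88 4
3.33333333333333 3.33333333333333 3.33333333333333 90.00000000000000
5 5 85 5
10 10 10 70
12.6666666666667 62.0000000000000 12.6666666666667 12.6666666666667

MOTIF ZEB1
A C G T
5 85 5 5
90.00000000000000 3.33333333333333 3.33333333333333 3.33333333333333
4 88 4 4
2.66666666666667 92.00000000000000 2.66666666666667 2.66666666666667
3.33333333333333 3.33333333333333 3.33333333333333 90.00000000000000
5 5 85 5
11.6666666666667 11.6666666666667 65.0000000000000 11.6666666666667
14 14 14 58

MOTIF FOXM1
A C G T
6.66666666666667 6.66666666666667 6.66666666666667 80.00000000000000
90.00000000000000 3.33333333333333 3.33333333333333 3.33333333333333
92.00000000000000 2.66666666666667 2.66666666666667 2.66666666666667
88 4 4 4
5 85 5 5
90.00000000000000 3.33333333333333 3.33333333333333 3.33333333333333
64 12 12 12
15 15 15 55

MOTIF SOX9
A C G T
88 4 4 4
90.00000000000000 3.33333333333333 3.33333333333333 3.33333333333333
5 85 5 5
92.00000000000000 2.66666666666667 2.66666666666667 2.66666666666667
90.00000000000000 3.33333333333333 3.33333333333333 3.33333333333333
6.66666666666667 6.66666666666667 6.66666666666667 80.00000000000000
13.3333333333333 13.3333333333333 60.0000000000000 13.3333333333333
11.3333333333333 11.3333333333333 66.0000000000000 11.3333333333333

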