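ATOM      1  CA  GLY A   1       2.300   0.000   0.000  1.00 23.27              
ATOM      2  CA  GLY A   2      -0.399   2.265   1.500  1.00 26.18              
ATOM      3  CA  GLY A   3      -2.161  -0.787   3.000  1.00 28.41              
ATOM      4  CA  GLY A   4       1.150  -1.992   4.500  1.00 29.72              
ATOM      5  CA  GLY A   5       1.762   1.478   6.000  1.00 29.95              
ATOM      6  CA  GLY A   6      -1.762   1.478   7.500  1.00 29.09              
ATOM      7  CA  GLY A   7      -1.150  -1.992   9.000  1.00 27.23              
ATOM      8  CA  GLY A   8       2.161  -0.787  10.500  1.00 24.57              
ATOM      9  CA  GLY A   9       0.399   2.265  12.000  1.00 21.41              
ATOM     10  CA  GLY A  10      -2.300   0.000  13.500  1.00 18.09              
ATOM     11  CA  GLY A  11       0.399  -2.265  15.000  1.00 14.99              
ATOM     12  CA  GLY A  12       2.161   0.787  16.500  1.00 12.43              
ATOM     13  CA  GLY A  13      -1.150   1.992  18.000  1.00 10.71              
ATOM     14  CA  GLY A  14      -1.762  -1.478  19.500  1.00 10.01              
ATOM     15  CA  GLY A  15       1.762  -1.478  21.000  1.00 10.41              
ATOM     16  CA  GLY A  16       1.150   1.992  22.500  1.00 11.87              
ATOM     17  CA  GLY A  17      -2.161   0.787  24.000  1.00 14.22              
ATOM     18  CA  GLY A  18      -0.399  -2.265  25.500  1.00 17.21              
ATOM     19  CA  GLY A  19       2.300  -0.000  27.000  1.00 20.50              
ATOM     20  CA  GLY A  20      -0.399   2.265  28.500  1.00 23.74              
END   
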