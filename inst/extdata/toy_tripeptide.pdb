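ATOM      1  N   ALA A  10       1.884  -1.319  -4.275  1.00  0.00           N  
ATOM      2  CA  ALA A  10       2.300   0.000  -3.750  1.00  0.00           C  
ATOM      3  C   ALA A  10       1.884   1.319  -3.225  1.00  0.00           C  
ATOM      4  O   ALA A  10       2.286   1.601  -2.097  1.00  0.00           O  
ATOM      5  CB  ALA A  10       3.739   0.000  -4.270  1.00  0.00           C  
ATOM      6  N   SER A  11       0.972   2.085  -2.775  1.00  0.00           N  
ATOM      7  CA  SER A  11      -0.399   2.265  -2.250  1.00  0.00           C  
ATOM      8  C   SER A  11      -1.626   1.626  -1.725  1.00  0.00           C  
ATOM      9  O   SER A  11      -1.973   1.973  -0.597  1.00  0.00           O  
ATOM     10  CB  SER A  11      -0.649   3.682  -2.770  1.00  0.00           C  
ATOM     11  OG  SER A  11      -0.878   4.979  -3.247  1.00  0.00           O  
ATOM     12  N   ASP A  12      -2.222   0.595  -1.275  1.00  0.00           N  
ATOM     13  CA  ASP A  12      -2.161  -0.787  -0.750  1.00  0.00           C  
ATOM     14  C   ASP A  12      -1.319  -1.884  -0.225  1.00  0.00           C  
ATOM     15  O   ASP A  12      -1.601  -2.286   0.903  1.00  0.00           O  
ATOM     16  CB  ASP A  12      -3.513  -1.279  -1.270  1.00  0.00           C  
ATOM     17  CG  ASP A  12      -4.724  -1.719  -1.736  1.00  0.00           C  
ATOM     18  OD1 ASP A  12      -4.922  -2.962  -1.957  1.00  0.00           O  
ATOM     19  OD2 ASP A  12      -5.675  -0.895  -1.957  1.00  0.00           O  
END   
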