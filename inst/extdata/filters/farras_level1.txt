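# First-stage analysis lowpass filters for the dual tree (Farras
# nearly-symmetric orthonormal pair).  Column 1: tree A, column 2: tree B
# (tree A delayed by one sample).  Highpass filters are derived by the
# quadrature-mirror rule in code.
 0.00000000000000  0.01122679215254
-0.08838834764832  0.01122679215254
 0.08838834764832 -0.08838834764832
 0.69587998903400  0.08838834764832
 0.69587998903400  0.69587998903400
 0.08838834764832  0.69587998903400
-0.08838834764832  0.08838834764832
 0.01122679215254 -0.08838834764832
 0.01122679215254  0.00000000000000
 0.00000000000000  0.00000000000000
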