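# Q-shift 10-tap analysis lowpass filter, tree A, for dual-tree levels >= 2.
# Tree B is the time reverse.
 0.03516384
 0.00000000
-0.08832942
 0.23389032
 0.76027237
 0.58751830
 0.00000000
-0.11430184
 0.00000000
 0.00000000
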