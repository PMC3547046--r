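# Q-shift 14-tap analysis lowpass filter, tree A, for dual-tree levels >= 2.
# Tree B is the time reverse (quarter-sample group delays 
# (N-1)/2 -/+ 1/4, i.e. a half-sample offset between the trees).
 0.00325314
-0.00388321
 0.03466035
-0.03887280
-0.11720389
 0.27529538
 0.75614564
 0.56881042
 0.01186609
-0.10671180
 0.02382538
 0.01702522
-0.00543948
-0.00455690
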