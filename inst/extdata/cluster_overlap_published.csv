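cluster,G1,G2,G3
C1,0,11,0
C2,39,4,2
C3,5,1,0
C4,1,0,0
C5,11,12,0
C6,8,2,1
C7,4,0,1
C8,0,1,0
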