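trait,population,A,PD_D,OD,uncertain
FB,IF2,0,3,16,0
FB,HSBCF1,2,0,10,0
FB,MARBCF1,6,2,3,0
BN,IF2,0,8,7,0
BN,HSBCF1,6,1,6,0
BN,MARBCF1,7,0,7,0
BW,IF2,0,3,12,0
BW,HSBCF1,10,0,9,0
BW,MARBCF1,11,0,4,0
LP,IF2,0,5,17,2
LP,HSBCF1,7,0,7,0
LP,MARBCF1,9,1,8,0
SY,IF2,0,2,6,0
SY,HSBCF1,5,0,19,0
SY,MARBCF1,5,1,11,0
LY,IF2,0,4,9,0
LY,HSBCF1,4,1,12,0
LY,MARBCF1,9,2,6,0
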