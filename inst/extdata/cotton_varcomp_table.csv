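population,trait,vG,vGE,vE,H2_printed
RIL,FB,0.287,0.000,1.804,56.00
RIL,BN,1.340,0.000,8.243,56.54
RIL,BW,0.081,0.020,0.421,58.45
RIL,LP,1.843,0.000,2.338,86.31
RIL,SY,3944.200,0.002,20321.300,60.83
RIL,LY,638.499,0.001,2956.910,63.34
IF2,FB,0.347,0.011,3.139,46.79
IF2,BN,1.775,0.260,14.364,48.82
IF2,BW,0.154,0.017,0.787,60.01
IF2,LP,1.062,0.604,4.924,58.09
IF2,SY,10632.730,2385.370,44067.000,63.53
IF2,LY,1643.570,479.871,6421.440,64.05
HSBCF1,FB,0.315,0.130,1.694,40.84
HSBCF1,BN,1.589,0.744,7.424,43.77
HSBCF1,BW,0.072,0.027,0.412,39.73
HSBCF1,LP,1.192,0.199,2.277,65.81
HSBCF1,SY,4952.399,147.787,19672.600,49.99
HSBCF1,LY,785.839,4.376,2875.500,52.19
MARBCF1,FB,0.339,0.240,3.390,41.20
MARBCF1,BN,1.585,0.938,14.863,43.11
MARBCF1,BW,0.101,0.031,0.824,47.65
MARBCF1,LP,1.185,0.038,4.549,67.21
MARBCF1,SY,5590.720,1793.300,44491.400,48.19
MARBCF1,LY,835.094,169.841,5743.140,52.34
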