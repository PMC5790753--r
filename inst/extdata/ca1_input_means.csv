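segment,region,hemisphere,mean_csi,se
proximal,CA3a,ipsilateral,4.00,0.55
proximal,CA3b,ipsilateral,3.14,0.31
proximal,CA3c,ipsilateral,1.89,0.23
proximal,CA3a,contralateral,1.79,0.13
proximal,CA3b,contralateral,1.20,0.11
proximal,CA3c,contralateral,0.70,0.14
proximal,LEC,ipsilateral,0.49,0.08
proximal,MEC,ipsilateral,1.51,0.24
proximal,SUB,ipsilateral,0.31,0.04
proximal,PreParaSUB,ipsilateral,0.53,0.11
proximal,pCA1,contralateral,0.00,0.00
proximal,mCA1,contralateral,0.00,0.00
proximal,dCA1,contralateral,0.01,0.01
proximal,MedianRaphe,ipsilateral,0.12,0.01
proximal,MS-DB,ipsilateral,1.69,0.23
intermediate,CA3a,ipsilateral,2.61,0.50
intermediate,CA3b,ipsilateral,2.32,0.41
intermediate,CA3c,ipsilateral,1.06,0.24
intermediate,CA3a,contralateral,1.15,0.13
intermediate,CA3b,contralateral,1.03,0.13
intermediate,CA3c,contralateral,0.51,0.05
intermediate,LEC,ipsilateral,0.62,0.04
intermediate,MEC,ipsilateral,0.87,0.10
intermediate,SUB,ipsilateral,0.55,0.05
intermediate,PreParaSUB,ipsilateral,0.28,0.04
intermediate,pCA1,contralateral,0.01,0.01
intermediate,mCA1,contralateral,0.04,0.02
intermediate,dCA1,contralateral,0.13,0.06
intermediate,MedianRaphe,ipsilateral,0.05,0.01
intermediate,MS-DB,ipsilateral,0.88,0.06
distal,CA3a,ipsilateral,0.61,0.10
distal,CA3b,ipsilateral,1.23,0.13
distal,CA3c,ipsilateral,0.60,0.08
distal,CA3a,contralateral,0.34,0.12
distal,CA3b,contralateral,0.76,0.19
distal,CA3c,contralateral,0.43,0.14
distal,LEC,ipsilateral,0.98,0.11
distal,MEC,ipsilateral,0.45,0.07
distal,SUB,ipsilateral,1.33,0.27
distal,PreParaSUB,ipsilateral,0.24,0.06
distal,pCA1,contralateral,0.01,0.00
distal,mCA1,contralateral,0.08,0.02
distal,dCA1,contralateral,0.23,0.04
distal,MedianRaphe,ipsilateral,0.03,0.01
distal,MS-DB,ipsilateral,1.43,0.17
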