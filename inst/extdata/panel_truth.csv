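sample,component,true_vcn
A,VCN4,4
B,VCN2,2
C,VCN0,0
D,VCN3,3
E,VCN1,1
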