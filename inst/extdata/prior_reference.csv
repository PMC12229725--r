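sample,chrom,position
A,chr1,45634499
A,chr1,160440748
A,chr4,5612738
A,chr22,42082676
B,chr6,45210754
B,chr22,40844112
D,chr3,130934986
D,chr14,22564447
D,chr15,25124969
E,chr3,35632784
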