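sample,chrom,tsd_start,tsd_end,duplication_sequence,gene,region
A,chr1,45634495,45634499,GTTTGG,PBP1L1,intron
A,chr1,160440776,160440780,TGTAC,,intergenic
A,chr16,2259698,2259702,TTAGC,RNPS1,intron
A,chr22,42082672,42082676,GTTTT,SMDT1,intron
B,chr6,45210831,45210835,CAGAC,SUPT3H,intron
B,chr22,40844212,40844216,GATAC,ST13,intron
D,chr3,130934987,130934991,CACCC,ATP2C1,intron
D,chr14,22564447,22564451,CAAAT,,intergenic
D,chr15,25124969,25124973,CATAT,SNHG14,3'UTR
E,chr3,35632785,35632789,ATAAC,,intergenic
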