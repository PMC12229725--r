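chrom,start,end,gene,region
chr1,45632000,45637000,PBP1L1,intron
chr16,2258000,2261000,RNPS1,intron
chr22,42081000,42084000,SMDT1,intron
chr6,45209000,45212000,SUPT3H,intron
chr22,40843000,40846000,ST13,intron
chr3,130933000,130936000,ATP2C1,intron
chr15,25123000,25126000,SNHG14,3'UTR
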