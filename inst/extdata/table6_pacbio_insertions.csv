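chrom,tsd_start,tsd_end,duplication_sequence,pbsv_id,insertion_length_bp
chr22,42082672,42082676,GTTTT,pbsv.INS.54478,4160
chr16,2259698,2259702,GCTAA,pbsv.INS.43848,4160
chr1,160440776,160440780,GTACA,pbsv.INS.2597,4160
chr1,45634495,45634499,GTTTG,pbsv.INS.110,4160
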