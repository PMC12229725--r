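sample,lab_id,site_string
A,lab9,"chr1:45,634,495(+) - 45,634,499(−)"
A,lab9,"chr1:160,440,776(+) - 160,440,780(−)"
A,lab9,"chr16:2,259,698(+) - 2,259,702(−)"
A,lab9,"chr22:42,082,672(+) - 42,082,676(−)"
A,lab10,"chr1:45,634,499-45,634,495"
A,lab10,"chr1:160,440,776-160,440,780"
A,lab10,"chr16:2,259,702-2,259,698"
A,lab10,"chr22:42,082,676-42,082,672"
A,lab11,"chr1:45,634,495(+)"
A,lab11,"chr1:160,440,780(−)"
A,lab11,"chr16:2,259,702(−)"
A,lab11,"chr22:42,082,672(+)"
B,lab9,"chr6:45,210,831(+) - 45,210,835(−)"
B,lab9,"chr22:40,844,212(+) - 40,844,216(−)"
B,lab10,"chr6:45,210,831- 45,210,835"
B,lab10,"Chr22: 40,844,216-40,844,212"
B,lab11,"chr6:45,210,835(−)"
B,lab11,"chr22:40,844,212(+)"
C,lab9,not detected
C,lab10,not detected
C,lab11,not detected
D,lab9,"chr3:130,934,987(+) - 130,934,991(−)"
D,lab9,"chr14:22,564,447(+) - 22,564,451(−)"
D,lab9,"chr15:25,124,969(+) - 25,124,973(−)"
D,lab10,"chr3:130,934,991-130,934,987"
D,lab10,"chr14:22,564,447-22,564,451"
D,lab10,"chr15:25,124,969-25,124,973"
D,lab11,"chr3:130,934,987(+)"
D,lab11,"chr14:22,564,451(−)"
D,lab11,"chr15:25,124,973(−)"
E,lab9,"chr3:35,632,785(+) - 35,632,789(−)"
E,lab10,"chr3:35,632,785-35,632,789"
E,lab11,"chr3:35,632,789(−)"
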