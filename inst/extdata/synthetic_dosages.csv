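subject_id,rs0822905,rs0018726,rs0788079,rs0711788,rs0234672,rs0307487,rs0776506,rs0088920,rs0131151,rs0787566,rs0022508,rs0593846,rs0077694,rs0074717,rs0301580,rs0470245,rs0984099,rs0748803
S001,1,1,0,0,2,1,0,0,0,0,0,1,0,1,0,2,0,0
S002,1,0,0,0,1,1,2,0,1,1,0,1,1,1,0,1,0,1
S003,0,0,0,1,1,0,0,2,1,0,1,1,0,0,1,1,0,0
S004,1,0,0,0,1,1,0,1,1,0,1,1,1,1,1,0,1,0
S005,1,1,1,0,0,1,0,0,2,1,1,1,1,0,2,1,0,0
S006,1,0,0,1,1,2,1,0,0,1,1,1,0,1,0,0,1,0
S007,0,1,0,1,1,2,1,0,0,1,1,0,1,0,1,0,1,2
S008,1,0,1,0,0,1,0,0,1,1,0,0,1,1,1,0,0,0
S009,0,0,0,1,0,0,1,0,2,0,1,1,2,0,0,1,0,0
S010,2,1,0,0,1,0,1,1,1,1,1,1,0,1,0,1,0,0
S011,1,0,1,1,2,2,0,0,2,2,1,1,0,0,1,0,1,1
S012,2,0,1,1,0,1,2,1,1,0,1,0,2,0,0,1,0,0
S013,0,0,0,2,0,0,0,0,1,1,1,1,0,1,1,2,0,0
S014,2,0,0,0,0,0,1,1,1,0,1,0,1,0,0,1,0,0
S015,1,1,0,0,0,1,0,1,1,0,0,1,1,0,1,1,0,0
S016,2,1,0,1,0,0,2,0,0,1,0,0,1,0,2,0,0,0
S017,0,0,0,1,0,0,1,0,0,1,1,1,0,1,1,0,0,0
S018,0,1,0,0,0,0,1,0,0,1,1,1,1,0,2,1,1,1
S019,2,0,0,0,1,0,1,0,1,0,0,1,0,1,1,2,2,1
S020,1,1,1,0,1,0,0,0,0,0,1,1,1,2,1,1,0,0
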