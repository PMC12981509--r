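disease_id,Commonality,Duration,QALYs lost,Mortality,Disease modification,Adverse events,Route of administration,Frequency of administration,Cost to patients,Robust supply,Regulatory barriers
MONDO:9000001,5,2,4,3,3,2,1,1,3,1,1
MONDO:9000002,1,5,1,5,5,2,3,5,5,4,3
MONDO:9000003,5,5,3,4,2,5,5,3,5,4,1
MONDO:9000004,5,5,2,5,4,3,1,1,4,4,1
MONDO:9000005,3,3,5,3,5,1,3,3,4,2,5
MONDO:9000006,2,4,2,5,2,2,1,1,3,3,2
MONDO:9000007,5,3,3,5,4,3,3,3,3,2,1
MONDO:9000008,5,4,1,5,1,1,5,2,5,4,1
MONDO:9000009,2,3,3,2,2,4,5,5,5,2,1
MONDO:9000010,4,4,1,4,3,4,5,3,1,2,2
MONDO:9000011,3,5,4,5,3,5,4,5,3,1,1
MONDO:9000012,2,1,3,5,3,2,3,4,1,2,4
MONDO:9000013,2,2,5,5,4,1,4,2,2,5,1
MONDO:9000014,4,3,1,5,1,1,1,3,5,4,3
MONDO:9000015,5,4,3,3,2,1,4,5,5,1,5
MONDO:9000016,5,2,4,1,3,3,2,2,4,3,1
MONDO:9000017,3,4,4,2,3,5,3,5,4,5,1
MONDO:9000018,2,5,4,4,2,1,2,4,2,5,1
MONDO:9000019,5,1,1,5,5,4,2,3,2,2,3
MONDO:9000020,1,5,4,3,2,5,4,2,3,1,5
MONDO:9000021,3,2,3,3,2,4,1,2,1,3,1
MONDO:9000022,1,1,2,1,3,3,1,1,4,5,2
MONDO:9000023,1,3,5,5,3,5,5,1,5,5,3
MONDO:9000024,5,4,4,3,4,5,2,4,5,1,4
MONDO:9000025,2,5,2,2,1,5,5,5,5,2,2
MONDO:9000026,3,4,3,2,4,5,2,2,1,2,5
MONDO:9000027,4,2,4,5,4,2,5,3,1,5,5
MONDO:9000028,5,5,4,5,4,3,1,4,1,3,1
MONDO:9000029,4,5,1,4,2,3,1,1,3,1,5
MONDO:9000030,2,4,2,2,1,3,5,1,3,2,5
MONDO:9000031,1,3,1,2,4,5,4,5,3,1,1
MONDO:9000032,1,2,2,3,5,5,3,5,2,2,2
MONDO:9000033,5,1,5,4,2,2,2,3,5,5,3
MONDO:9000034,5,2,4,5,3,5,3,5,3,3,2
MONDO:9000035,5,2,4,5,5,5,1,1,3,2,5
MONDO:9000036,2,4,4,5,3,5,4,3,3,4,5
MONDO:9000037,2,5,3,1,3,3,3,2,1,4,3
MONDO:9000038,4,1,5,2,1,2,3,4,4,4,1
MONDO:9000039,3,2,5,5,5,2,5,1,1,2,3
MONDO:9000040,5,5,2,4,3,4,2,2,4,3,4
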