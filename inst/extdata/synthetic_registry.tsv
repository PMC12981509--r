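MONDO:9000001	synthetic disease 001	synthetic condition 001
MONDO:9000002	synthetic disease 002	synthetic condition 002
MONDO:9000003	synthetic disease 003	synthetic condition 003
MONDO:9000004	synthetic disease 004	synthetic condition 004
MONDO:9000005	synthetic disease 005	synthetic condition 005
MONDO:9000006	synthetic disease 006	synthetic condition 006
MONDO:9000007	synthetic disease 007	synthetic condition 007
MONDO:9000008	synthetic disease 008	synthetic condition 008
MONDO:9000009	synthetic disease 009	synthetic condition 009
MONDO:9000010	synthetic disease 010	synthetic condition 010
MONDO:9000011	synthetic disease 011	synthetic condition 011
MONDO:9000012	synthetic disease 012	synthetic condition 012
MONDO:9000013	synthetic disease 013	synthetic condition 013
MONDO:9000014	synthetic disease 014	synthetic condition 014
MONDO:9000015	synthetic disease 015	synthetic condition 015
MONDO:9000016	synthetic disease 016	synthetic condition 016
MONDO:9000017	synthetic disease 017	synthetic condition 017
MONDO:9000018	synthetic disease 018	synthetic condition 018
MONDO:9000019	synthetic disease 019	synthetic condition 019
MONDO:9000020	synthetic disease 020	synthetic condition 020
MONDO:9000021	synthetic disease 021	synthetic condition 021
MONDO:9000022	synthetic disease 022	synthetic condition 022
MONDO:9000023	synthetic disease 023	synthetic condition 023
MONDO:9000024	synthetic disease 024	synthetic condition 024
MONDO:9000025	synthetic disease 025	synthetic condition 025
MONDO:9000026	synthetic disease 026	synthetic condition 026
MONDO:9000027	synthetic disease 027	synthetic condition 027
MONDO:9000028	synthetic disease 028	synthetic condition 028
MONDO:9000029	synthetic disease 029	synthetic condition 029
MONDO:9000030	synthetic disease 030	synthetic condition 030
MONDO:9000031	synthetic disease 031	synthetic condition 031
MONDO:9000032	synthetic disease 032	synthetic condition 032
MONDO:9000033	synthetic disease 033	synthetic condition 033
MONDO:9000034	synthetic disease 034	synthetic condition 034
MONDO:9000035	synthetic disease 035	synthetic condition 035
MONDO:9000036	synthetic disease 036	synthetic condition 036
MONDO:9000037	synthetic disease 037	synthetic condition 037
MONDO:9000038	synthetic disease 038	synthetic condition 038
MONDO:9000039	synthetic disease 039	synthetic condition 039
MONDO:9000040	synthetic disease 040	synthetic condition 040
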