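{"Commonality":0.25,"Duration":0.5,"QALYs lost":0.75,"Mortality":1,"Disease modification":1,"Adverse events":0.75,"Route of administration":0.5,"Frequency of administration":0.25,"Cost to patients":0.25,"Robust supply":0.25,"Regulatory barriers":0.25}
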