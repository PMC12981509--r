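{"Commonality":{"type":"numeric","attribute":"prevalence_per_100k","cuts":[0.5,5,50,500],"direction":"decreasing","domain":[0,5000]},"Duration":{"type":"numeric","attribute":"typical_duration_years","cuts":[0.1,1,5,20],"direction":"increasing","domain":[0,80]},"QALYs lost":{"type":"numeric","attribute":"qaly_loss_fraction","cuts":[0.1,0.3,0.5,0.7],"direction":"increasing","domain":[0,1]},"Mortality":{"type":"numeric","attribute":"five_year_mortality_pct","cuts":[1,10,30,60],"direction":"increasing","domain":[0,100]},"Disease modification":{"type":"categorical","attribute":"soc_disease_modification","map":{"curative":1,"substantial":2,"moderate":3,"partial":4,"none":5}},"Adverse events":{"type":"categorical","attribute":"soc_adverse_event_burden","map":{"none":1,"mild":2,"moderate":3,"severe":4,"intolerable":5}},"Route of administration":{"type":"categorical","attribute":"admin_route","map":{"oral":1,"topical":2,"self_injection":3,"clinic_infusion":4,"implanted":5}},"Frequency of administration":{"type":"numeric","attribute":"admin_doses_per_week","cuts":[0.25,1,7,21],"direction":"increasing","domain":[0,56]},"Cost to patients":{"type":"categorical","attribute":"annual_cost_band","map":{"minimal":1,"low":2,"moderate":3,"high":4,"catastrophic":5}},"Robust supply":{"type":"categorical","attribute":"supply_robustness","map":{"robust":1,"mostly_stable":2,"occasional_shortage":3,"frequent_shortage":4,"chronic_shortage":5}},"Regulatory barriers":{"type":"categorical","attribute":"regulatory_barrier","map":{"none":1,"minimal":2,"moderate":3,"high":4,"prohibitive":5}}}
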