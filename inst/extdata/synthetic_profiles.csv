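disease_id,prevalence_per_100k,typical_duration_value,typical_duration_unit,qaly_loss_fraction,five_year_mortality_pct,soc_disease_modification,soc_adverse_event_burden,admin_route,admin_doses_per_week,annual_cost_band,supply_robustness,regulatory_barrier
MONDO:9000001,28.7414117960725,56.6171318339184,years,0.119288996886462,1.50781973893754,moderate,moderate,topical,0.289442462439183,catastrophic,occasional_shortage,high
MONDO:9000002,854.665471124463,14.6206231717952,years,0.833474380872212,11.8886621948332,partial,intolerable,implanted,20.2837622878142,moderate,robust,prohibitive
MONDO:9000003,3.86714151629712,0.90411915271543,years,0.0950002702418715,87.3382246121764,substantial,moderate,self_injection,0.232904433680233,minimal,occasional_shortage,none
MONDO:9000004,0.134941678494215,0.00424193469807506,years,0.677146488102153,39.9813469871879,substantial,intolerable,implanted,26.5156829860061,moderate,chronic_shortage,none
MONDO:9000005,19.0980104461778,5.07930034771562,years,0.387596610561013,47.1573634352535,moderate,none,topical,0.780672401422635,low,mostly_stable,none
MONDO:9000006,15.9936588536948,11.4496605109889,years,0.506554345181212,8.13554471149109,partial,moderate,clinic_infusion,41.5375369428657,high,frequent_shortage,prohibitive
MONDO:9000007,1247.47453816235,2.11909291055053,years,0.588393087964505,62.3627223353833,partial,mild,self_injection,0.140971143555362,moderate,frequent_shortage,prohibitive
MONDO:9000008,0.271306450827979,69.0417128056288,years,0.720581592386588,26.1242609610781,moderate,severe,clinic_infusion,9.57186261983588,moderate,chronic_shortage,high
MONDO:9000009,289.438884018455,0.741311319405213,years,0.183982448652387,7.29669012851082,curative,mild,oral,6.02458794927225,low,occasional_shortage,none
MONDO:9000010,1474.3600076763,0.331466842186637,years,0.283883513184264,44.9832602357492,none,none,oral,14.7502217078581,low,frequent_shortage,prohibitive
MONDO:9000011,0.0449948399327695,2.68873353023082,years,0.408977991808206,56.9374806317501,partial,intolerable,self_injection,0.442300136259291,minimal,mostly_stable,moderate
MONDO:9000012,39.5441519864835,15.5253776640166,years,0.0474726308370009,0.623297904618084,partial,intolerable,clinic_infusion,0.469975183892529,moderate,robust,high
MONDO:9000013,0.40766058571171,0.0388746345182881,years,0.660870601888746,14.5844360627234,moderate,none,self_injection,6.47359582502395,catastrophic,chronic_shortage,prohibitive
MONDO:9000014,15.1496430509724,79.4900488806888,years,0.222231487603858,56.4279008936137,curative,intolerable,self_injection,0.234497599944007,catastrophic,mostly_stable,moderate
MONDO:9000015,34.2797695088666,1.23638672195375,years,0.219539167033508,57.8937357268296,moderate,severe,implanted,19.2870483957231,catastrophic,chronic_shortage,moderate
MONDO:9000016,4.52200848306529,0.0618784737074748,years,0.0699060721090063,75.962850023061,partial,none,self_injection,21.6866953114513,catastrophic,frequent_shortage,prohibitive
MONDO:9000017,23.1670860585291,0.0241647371090949,years,0.519785756897181,78.2006959151477,substantial,intolerable,implanted,7.73572271829471,high,mostly_stable,high
MONDO:9000018,2782.40217035636,32.8733778232709,years,0.872444491251372,65.3259143233299,partial,moderate,clinic_infusion,4.11724071810022,minimal,chronic_shortage,moderate
MONDO:9000019,3.88241235062014,35.1702460087836,years,0.230012528644875,1.41893240087666,substantial,moderate,implanted,17.709038939327,catastrophic,frequent_shortage,high
MONDO:9000020,2.57447314495221,0.733259563264437,years,0.585139940166846,12.6418796507642,moderate,mild,self_injection,0.522776323196013,catastrophic,chronic_shortage,none
MONDO:9000021,0.724429330904968,1.03512781113386,years,0.0762442891485989,56.3194141862914,curative,intolerable,clinic_infusion,1.67672063177451,catastrophic,occasional_shortage,high
MONDO:9000022,130.075842130464,0.941416248492897,years,0.257671533105895,5.04909740900621,partial,none,self_injection,0.0604899571044371,minimal,mostly_stable,prohibitive
MONDO:9000023,0.135872427374125,4.84892795141786,years,0.988569879438728,96.9098225887865,moderate,moderate,topical,11.1769448663108,catastrophic,chronic_shortage,minimal
MONDO:9000024,4939.04678232502,39.7750749485567,years,0.632672727294266,39.9188254983164,curative,intolerable,topical,29.2389583624899,low,frequent_shortage,none
MONDO:9000025,317.58508059429,2.03933358378708,years,0.200935956789181,97.4498719442636,substantial,intolerable,clinic_infusion,0.502355509786867,minimal,occasional_shortage,high
MONDO:9000026,150.134206016082,73.7878457410261,years,0.641293999133631,0.893529210472479,partial,severe,self_injection,30.8099330929108,low,mostly_stable,prohibitive
MONDO:9000027,854.96934549883,1.15548484027386,years,0.045175587432459,28.1199466390535,none,mild,topical,13.7157513406128,low,occasional_shortage,high
MONDO:9000028,2.48759367293678,75.36192657426,years,0.989077435736544,29.5163206802681,curative,mild,oral,0.660284857382067,low,chronic_shortage,minimal
MONDO:9000029,402.724891749676,7.95901330653578,years,0.1897224414628,51.095291110687,substantial,mild,implanted,22.5325609478168,high,frequent_shortage,minimal
MONDO:9000030,0.0467360655311495,0.0803537423023954,years,0.442398868827149,59.8608069098555,substantial,none,self_injection,6.56915472773835,moderate,chronic_shortage,high
MONDO:9000031,46.3087830028962,0.0353472281713039,years,0.168497543688864,0.553941520629451,partial,intolerable,self_injection,31.0474035611842,moderate,robust,prohibitive
MONDO:9000032,0.0493815107038245,1.53712499979883,years,0.558915149187669,88.2009148783982,curative,mild,implanted,0.215693377132993,moderate,mostly_stable,minimal
MONDO:9000033,706.217838916928,1.97594836261123,years,0.397541031707078,0.178913114126772,curative,none,topical,0.405648526793811,minimal,mostly_stable,none
MONDO:9000034,29.6665575064253,0.934971809666604,years,0.402161269215867,9.6822797965724,substantial,none,topical,5.05335499672219,minimal,robust,high
MONDO:9000035,2.85801648185588,28.4374071424827,years,0.353310155356303,9.50326617667452,partial,severe,oral,39.1276003399398,catastrophic,frequent_shortage,prohibitive
MONDO:9000036,8.6171482456848,4.55398051720113,years,0.180006116488948,21.0544161405414,moderate,intolerable,implanted,0.037826149025932,minimal,robust,high
MONDO:9000037,0.404649563715793,5.69412199780345,years,0.381397773977369,38.4059655060992,none,mild,self_injection,2.82453757477924,moderate,frequent_shortage,none
MONDO:9000038,14.5629518222995,1.909089515917,years,0.0969963455805555,0.0882199450861663,partial,none,oral,10.71561126085,high,chronic_shortage,none
MONDO:9000039,0.391100476845168,0.0305131988367066,years,0.167309916391969,72.2934714425355,moderate,none,implanted,6.04223996633664,minimal,chronic_shortage,high
MONDO:9000040,2.85796484723687,3.45789522211999,years,0.738606608123519,2.5997140398249,curative,moderate,implanted,22.5268044592813,minimal,robust,high
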