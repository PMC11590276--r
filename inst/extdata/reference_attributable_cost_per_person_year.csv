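component,stage_1,stage_2,stage_3a,stage_3b,stage_4,stage_5
emergency,148,255,269,550,1028,2454
hospital_nondialysis,1515,2255,2470,4592,8400,19723
medication,1374,1172,577,831,1121,1780
primary_care,315,401,230,347,463,474
pathology,14,31,47,96,168,203
dialysis,0,0,0,0,0,36982
outpatient,0,0,15,156,274,942
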