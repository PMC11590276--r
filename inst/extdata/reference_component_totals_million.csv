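component,total_million
emergency,46
hospital_nondialysis,396
medication,84
primary_care,31
pathology,7
dialysis,130
outpatient,9
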