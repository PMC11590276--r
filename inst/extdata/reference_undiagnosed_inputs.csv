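stage,albuminuria_proportion,persistence,estimated,observed,per_person_cost,diagnosed_total_million
1,0.057,0.66,40363,8338,3367,704
2,0.097,0.66,33482,9179,4114,704
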