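participant_id,set_id,criterion_a,criterion_b,intensity,linguistic_label
expert_01,hazard,flooding,warming,7,Strongly more important
expert_01,hazard,drought,warming,3,Slightly more important
expert_01,hazard,warming,sea_level_rise,3,Slightly more important
expert_01,hazard,flooding,drought,5,Moderately more important
expert_01,hazard,flooding,sea_level_rise,7,Strongly more important
expert_01,hazard,drought,sea_level_rise,3,Slightly more important
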