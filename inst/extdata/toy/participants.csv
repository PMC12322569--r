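participant_id,age_years,sex,survey_weight,wave
P1,30,female,1,W01
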