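participant_id,diary_day,item_code,grams,kcal
P1,1,F001,100,NA
P1,1,F002,100,NA
P1,1,F003,100,NA
P1,1,F004,100,NA
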