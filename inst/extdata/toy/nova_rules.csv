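level,code,nova_group
item,F001,4
item,F002,1
item,F003,4
item,F004,1
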