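item_code,item_name,main_group_code,main_group_name,subgroup_code,subgroup_name,is_drink,is_toddler_food,is_home_prepared,contains_purchased_pastry_or_breadcrumbs_or_margarine,is_alcohol_containing,is_supplement
F001,Fixture F001,MG01,Group MG01,SG001,Subgroup SG001,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
F002,Fixture F002,MG01,Group MG01,SG001,Subgroup SG001,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
F003,Fixture F003,MG02,Group MG02,SG002,Subgroup SG002,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
F004,Fixture F004,MG02,Group MG02,SG002,Subgroup SG002,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
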