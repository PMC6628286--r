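item_name,teac_content,is_coffee
leafy_vegetables,9.0,FALSE
other_vegetables,4.5,FALSE
citrus_fruit,11.0,FALSE
other_fruit,6.5,FALSE
berries,28.0,FALSE
legumes,8.0,FALSE
nuts,45.0,FALSE
whole_grains,7.0,FALSE
olive_oil,2.0,FALSE
red_wine,14.0,FALSE
tea,8.5,FALSE
dark_chocolate,35.0,FALSE
fruit_juice,7.0,FALSE
coffee,22.0,TRUE
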