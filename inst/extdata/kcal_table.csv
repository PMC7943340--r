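snack_id,label,kcal
chocolate_bar,Chocolate bar,250
crisps,Portion of crisps,160
biscuits,Two sweet biscuits,120
cake,Slice of cake,350
candy,Portion of candy,90
salted_nuts,Portion of salted nuts,200
ice_cream,Ice cream,180
soft_drink,Glass of sugared soft drink,140
pastry,Filled pastry,300
fried_snack,Fried snack,290
cheese_cubes,Portion of cheese cubes,170
sausage_roll,Sausage roll,320
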