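"compound_id","smiles","atc_codes","source","mol_weight"
"R1","CCO","A02BC","toy",500
"R2","CCN","V08AB","toy",NA
"R3","CCC","V03AX","toy",NA
"R4","CCCC","V01AA;C07AB","toy",320
"R5","CCCCC","B01AC","toy",901
"R6","CCCCCC","N06AB","toy",900
"R7","CC.CC","J01CA","toy",410
"R8","","R03AC","toy",120
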