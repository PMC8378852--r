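name,smiles
toluene,Cc1ccccc1
1.4-dioxane,C1COCCO1
THF,C1CCOC1
2-Me-THF,CC1CCCO1
DMF,CN(C)C=O
DMSO,CS(C)=O
tert-butanol,CC(C)(C)O
water,O
DME,COCCOC
NMP,CN1CCCC1=O
acetonitrile,CC#N
o-xylene,Cc1ccccc1C
2-propanol,CC(C)O
benzene,c1ccccc1
DMAc,CC(=O)N(C)C
ethanol,CCO
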