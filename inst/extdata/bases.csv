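name,smiles,strength_rank
LiHMDS,[Li+].C[Si](C)(C)[N-][Si](C)(C)C,1
NaHMDS,[Na+].C[Si](C)(C)[N-][Si](C)(C)C,2
KOtBu,[K+].CC(C)(C)[O-],3
NaOtBu,[Na+].CC(C)(C)[O-],4
P1-tBu phosphazene,CC(C)(C)N=P(N(C)C)(N(C)C)N(C)C,5
KOH,[K+].[OH-],6
NaOH,[Na+].[OH-],7
K3PO4,[K+].[K+].[K+].[O-]P([O-])([O-])=O,8
Cs2CO3,[Cs+].[Cs+].[O-]C([O-])=O,9
K2CO3,[K+].[K+].[O-]C([O-])=O,10
Na2CO3,[Na+].[Na+].[O-]C([O-])=O,11
DBU,C1CCC2=NCCCN2CC1,12
triethylamine,CCN(CC)CC,13
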