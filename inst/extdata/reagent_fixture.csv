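name,species,expected_role,expected_kind
toluene,Cc1ccccc1,solvent,
1.4-dioxane,C1COCCO1,solvent,
THF,C1CCOC1,solvent,
DMF,CN(C)C=O,solvent,
DMSO,CS(C)=O,solvent,
water,O,solvent,
toluene (by name),toluene,solvent,
DME (by name),DME,solvent,
NaOtBu,[Na+].CC(C)(C)[O-],base,
KOtBu,[K+].CC(C)(C)[O-],base,
Cs2CO3,[Cs+].[Cs+].[O-]C([O-])=O,base,
K2CO3,[K+].[K+].[O-]C([O-])=O,base,
K3PO4,[K+].[K+].[K+].[O-]P([O-])([O-])=O,base,
P1-tBu phosphazene,CC(C)(C)N=P(N(C)C)(N(C)C)N(C)C,base,
LiHMDS,[Li+].C[Si](C)(C)[N-][Si](C)(C)C,base,
KOH,[K+].[OH-],base,
DBU,C1CCC2=NCCCN2CC1,base,
NaOtBu (by name),NaOtBu,base,
PPh3,c1ccc(P(c2ccccc2)c2ccccc2)cc1,ligand,phosphine
P(t-Bu)3,CC(C)(C)P(C(C)(C)C)C(C)(C)C,ligand,phosphine
PCy3,C1CCC(CC1)P(C2CCCCC2)C3CCCCC3,ligand,phosphine
XPhos,CC(C)c1cc(C(C)C)c(-c2ccccc2P(C2CCCCC2)C2CCCCC2)c(C(C)C)c1,ligand,phosphine
SPhos,COc1cccc(OC)c1-c1ccccc1P(C1CCCCC1)C1CCCCC1,ligand,phosphine
DavePhos,CN(C)c1ccccc1-c1ccccc1P(C1CCCCC1)C1CCCCC1,ligand,phosphine
BINAP,c1ccc(P(c2ccccc2)c2ccc3ccccc3c2-c2c(P(c3ccccc3)c3ccccc3)ccc3ccccc23)cc1,ligand,phosphine
Xantphos,CC1(C)c2cccc(P(c3ccccc3)c3ccccc3)c2Oc2c(P(c3ccccc3)c3ccccc3)cccc21,ligand,phosphine
Triisobutylphosphatrane,P12N(CC(C)C)CCN(CCN1CC(C)C)CCN2CC(C)C,ligand,phosphine
triethyl phosphite,CCOP(OCC)OCC,ligand,phosphine
PCl3,ClP(Cl)Cl,generic,
phosphoryl chloride,O=P(Cl)(Cl)Cl,generic,
IPr hydrochloride,CC(C)c1cccc(C(C)C)c1[n+]1ccn(-c2c(C(C)C)cccc2C(C)C)c1.[Cl-],ligand,NHC
IPr carbene,CC(C)c1cccc(C(C)C)c1N1[C]N(c2c(C(C)C)cccc2C(C)C)C=C1,ligand,NHC
SIPr hydrochloride,CC(C)c1cccc(C(C)C)c1[N+]1=CN(c2c(C(C)C)cccc2C(C)C)CC1.[Cl-],ligand,NHC
imidazole,c1c[nH]cn1,generic,
Pd(OAc)2,CC(=O)O[Pd]OC(C)=O,metal_source,
PdCl2,Cl[Pd]Cl,metal_source,
Pd(PPh3)4,[Pd]([P](c1ccccc1)(c1ccccc1)c1ccccc1)([P](c1ccccc1)(c1ccccc1)c1ccccc1)([P](c1ccccc1)(c1ccccc1)c1ccccc1)[P](c1ccccc1)(c1ccccc1)c1ccccc1,metal_source,
CuI,[Cu]I,metal_source,
dibenzylideneacetone,O=C(C=Cc1ccccc1)C=Cc1ccccc1,generic,
18-crown-6,C1COCCOCCOCCOCCOCCO1,generic,
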