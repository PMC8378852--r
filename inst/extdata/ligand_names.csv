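name,smiles
PPh3,c1ccc(P(c2ccccc2)c2ccccc2)cc1
P(t-Bu)3,CC(C)(C)P(C(C)(C)C)C(C)(C)C
PCy3,C1CCC(CC1)P(C2CCCCC2)C3CCCCC3
P(o-tol)3,Cc1ccccc1P(c1ccccc1C)c1ccccc1C
XPhos,CC(C)c1cc(C(C)C)c(-c2ccccc2P(C2CCCCC2)C2CCCCC2)c(C(C)C)c1
SPhos,COc1cccc(OC)c1-c1ccccc1P(C1CCCCC1)C1CCCCC1
DavePhos,CN(C)c1ccccc1-c1ccccc1P(C1CCCCC1)C1CCCCC1
BINAP,c1ccc(P(c2ccccc2)c2ccc3ccccc3c2-c2c(P(c3ccccc3)c3ccccc3)ccc3ccccc23)cc1
Xantphos,CC1(C)c2cccc(P(c3ccccc3)c3ccccc3)c2Oc2c(P(c3ccccc3)c3ccccc3)cccc21
Triisobutylphosphatrane,P12N(CC(C)C)CCN(CCN1CC(C)C)CCN2CC(C)C
dppp,c1ccc(P(CCCP(c2ccccc2)c2ccccc2)c2ccccc2)cc1
IPr-HCl,CC(C)c1cccc(C(C)C)c1[n+]1ccn(-c2c(C(C)C)cccc2C(C)C)c1.[Cl-]
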