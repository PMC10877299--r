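# Hydrogen-suppressed structures of the 16 anti-hepatitis study drugs.
# Format: SMILES <TAB> drug name. See drug_provenance.csv for curation notes.
C=C1[C@@H](n2cnc3c2N=C(N)NC3=O)C[C@H](O)[C@@H]1CO	Baraclude
CC(=O)Nc1ccc(O)cc1	Acetaminophen
C=C[C@@H]1CC(F)(F)COc2ccc3ncc(nc3c2)O[C@@H]2C[C@H](C(=O)N[C@]1(C1CC1)C(=O)NS(=O)(=O)C1CC1)N(C2)C(=O)[C@H](NC(=O)OC1(CC1)C(F)F)C(C)(C)C	Glecaprevir
COC(=O)N[C@@H](C(C)C)C(=O)N1CCC[C@H]1c1ncc(-c2ccc(-c3ccc(-c4cnc([C@@H]5CCCN5C(=O)[C@@H](NC(=O)OC)C(C)C)[nH]4)cc3)cc2)[nH]1	Daclatasvir
CC(C)(C)C(=O)OCOP(=O)(COCCn1cnc2c(N)ncnc21)OCOC(=O)C(C)(C)C	Adifovir Dipivoxil
Nc1ccn([C@@H]2CS[C@H](CO)O2)c(=O)n1	Epivir-HBV
CCOC(=O)C1=C(CCN2CCOCC2)NC(c2nccs2)=N[C@H]1c1cc(F)ccc1Br	Morphothiadin
CC(C)OC(=O)[C@H](C)N[P@](=O)(OC[C@H]1O[C@@H](n2ccc(=O)[nH]c2=O)[C@](C)(F)[C@@H]1O)Oc1ccccc1	Sofosbuvir
Fc1ccc(N2[C@@H](c3ccc(-c4ccc5nc([C@@H]6CCCN6C(=O)[C@@H](NC(=O)OC)C(C)C)[nH]c5c4)cc3)CC[C@H]2c2ccc(-c3cc4nc([C@@H]5CCCN5C(=O)[C@@H](NC(=O)OC)C(C)C)[nH]c4c(F)c3OC(F)F)cc2)c(F)c1	Pibrentasvir
CC(C)c1nc(CN(C)C(=O)N[C@@H](C(C)C)C(=O)N[C@@H](Cc2ccccc2)C[C@H](O)[C@H](Cc2ccccc2)NC(=O)OCc2cncs2)cs1	Ritonavir
COC(=O)N[C@@H](C(C)C)C(=O)N1CCC[C@H]1C(=O)Nc1ccc([C@H]2CC[C@@H](c3ccc(NC(=O)[C@@H]4CCCN4C(=O)[C@@H](NC(=O)OC)C(C)C)cc3)N2c2ccc(C(C)(C)C)cc2)cc1	Ombitasvir
OC[C@H]1O[C@@H](n2cnc(C(N)=O)n2)[C@H](O)[C@@H]1O	Ribavirin
Cc1cn([C@H]2C[C@@H](O)[C@H](CO)O2)c(=O)[nH]c1=O	Telbivudine
CC(C)OC(=O)[C@H](C)N[P@](=O)(CO[C@H](C)Cn1cnc2c(N)ncnc21)Oc1ccccc1	Tenofovir alafenamide
C=C[C@@H]1CC(F)(F)C(F)(F)COc2ccc3ncc(nc3c2)O[C@@H]2C[C@H](C(=O)N[C@]1(C1CC1)C(=O)NS(=O)(=O)C1(C)CC1)N(C2)C(=O)[C@H](NC(=O)OC(C)(C)C)C(C)(C)C	Voxilaprevir
COC(=O)N[C@@H](c1ccccc1)C(=O)N1CCC[C@H]1c1cnc([nH]1)-c1ccc2cc3c(cc2c1)C(C)Oc1cc2[nH]c(nc2cc1C3)[C@@H]1C[C@H](COC)N1C(=O)[C@@H](NC(=O)OC)C(C)C	Velpatasvir
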