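compound_id,target,smiles,formula,dG_kcal_mol
huperzine_A,AChE,CC=C1C2(N)C3C=CC(=O)NC=3CC1C=C(C)C2,C15H18N2O,-7.9
galantamine,AChE,COc1ccc2c3c1O[C@@H]1C[C@H](O)C=C[C@]13CCN(C)C2,C17H21NO3,-4.9
donepezil,AChE,COc1cc2c(cc1OC)C(=O)C(CC1CCN(Cc3ccccc3)CC1)C2,C24H29NO3,-10.2
2WF,GSK3b,O=C(Nc1cc(-c2ccc3ccncc3c2)ccn1)C1CC1,C18H15N3O,-7.1
paroxetine,SERT,Fc1ccc(cc1)[C@@H]1CCNC[C@H]1COc1ccc2OCOc2c1,C19H20FNO3,-10.8
sertraline,SERT,CN[C@H]1CC[C@@H](c2ccc(Cl)c(Cl)c2)c2ccccc21,C17H17Cl2N,-9.1
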