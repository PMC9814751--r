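# Accessible cores with reactive handles (SMILES id)
OC(=O)c1ccc(cc1)-c1c2ccc(n2)c(-c2ccc(cc2)C(O)=O)c2ccc([nH]2)c(-c2ccc(cc2)C(O)=O)c2ccc(n2)c(-c2ccc(cc2)C(O)=O)c2ccc1[nH]2 tcpp
Oc1ccc(cc1)-c1c2ccc(n2)c(-c2ccc(O)cc2)c2ccc([nH]2)c(-c2ccc(O)cc2)c2ccc(n2)c(-c2ccc(O)cc2)c2ccc1[nH]2 thpp
OC(=O)c1ccccc1 benzoic_acid
Oc1ccccc1 phenol
OC(=O)c1ccc(O)cc1 hba
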