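{
  "comment": "Synthetic ChEMBL-style activity listing for offline demos and tests; hand-written, not a saved service response.",
  "activities": [
    {"molecule_chembl_id": "CHEMBL0000001", "canonical_smiles": "CC(=O)Oc1ccccc1C(=O)O", "standard_type": "Ki", "standard_value": "5200", "standard_units": "nM", "document_year": 2012},
    {"molecule_chembl_id": "CHEMBL0000002", "canonical_smiles": "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "standard_type": "Ki", "standard_value": "310", "standard_units": "nM", "document_year": 2014},
    {"molecule_chembl_id": "CHEMBL0000003", "canonical_smiles": "CN1CCC[C@H]1c1cccnc1", "standard_type": "Ki", "standard_value": "45", "standard_units": "nM", "document_year": 2015},
    {"molecule_chembl_id": "CHEMBL0000004", "canonical_smiles": "NCCc1c[nH]c2ccccc12", "standard_type": "Ki", "standard_value": "150", "standard_units": "nM", "document_year": 2016},
    {"molecule_chembl_id": "CHEMBL0000005", "canonical_smiles": "CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc12", "standard_type": "Ki", "standard_value": "14", "standard_units": "nM", "document_year": 2015},
    {"molecule_chembl_id": "CHEMBL0000006", "canonical_smiles": "CN(C)CCCN1c2ccccc2CCc2ccccc12", "standard_type": "Ki", "standard_value": "38", "standard_units": "nM", "document_year": 2014},
    {"molecule_chembl_id": "CHEMBL0000007", "canonical_smiles": "CC(C)NCC(O)COc1cccc2ccccc12", "standard_type": "Ki", "standard_value": "88", "standard_units": "nM", "document_year": 2016},
    {"molecule_chembl_id": "CHEMBL0000008", "canonical_smiles": "Oc1ccc(CCN2CCCCC2)cc1", "standard_type": "Ki", "standard_value": "230", "standard_units": "nM", "document_year": 2011},
    {"molecule_chembl_id": "CHEMBL0000011", "canonical_smiles": "CC(=O)Nc1ccc(O)cc1", "standard_type": "Ki", "standard_value": "8400", "standard_units": "nM", "document_year": 2011},
    {"molecule_chembl_id": "CHEMBL0000012", "canonical_smiles": "NCCc1ccc(O)c(O)c1", "standard_type": "Ki", "standard_value": "980", "standard_units": "nM", "document_year": 2010},
    {"molecule_chembl_id": "CHEMBL0000013", "canonical_smiles": "CNC[C@H](O)c1ccc(O)c(O)c1", "standard_type": "Ki", "standard_value": "62", "standard_units": "nM", "document_year": 2017},
    {"molecule_chembl_id": "CHEMBL0000014", "canonical_smiles": "Clc1ccccc1-c1nc2ccccc2[nH]1", "standard_type": "Ki", "standard_value": "21", "standard_units": "nM", "document_year": 2018},
    {"molecule_chembl_id": "CHEMBL0000015", "canonical_smiles": "COc1ccc2cc(ccc2c1)C(C)C(=O)O", "standard_type": "Ki", "standard_value": "77", "standard_units": "nM", "document_year": 2013},
    {"molecule_chembl_id": "CHEMBL0000016", "canonical_smiles": "CC(N)Cc1ccccc1", "standard_type": "Ki", "standard_value": "5600", "standard_units": "nM", "document_year": 2014},
    {"molecule_chembl_id": "CHEMBL0000017", "canonical_smiles": "OCCN1CCN(CC1)CCCN1c2ccccc2Sc2ccc(Cl)cc12", "standard_type": "Ki", "standard_value": "9", "standard_units": "nM", "document_year": 2016},
    {"molecule_chembl_id": "CHEMBL0000018", "canonical_smiles": "COc1cc2c(cc1OC)C(=O)C(CC1CCN(CC1)Cc1ccccc1)C2", "standard_type": "Ki", "standard_value": "6", "standard_units": "nM", "document_year": 2019},
    {"molecule_chembl_id": "CHEMBL0000019", "canonical_smiles": "CC(CS)C(=O)N1CCCC1C(=O)O", "standard_type": "Ki", "standard_value": "1900", "standard_units": "nM", "document_year": 2013},
    {"molecule_chembl_id": "CHEMBL0000020", "canonical_smiles": "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1", "standard_type": "Ki", "standard_value": "520", "standard_units": "nM", "document_year": 2015},
    {"molecule_chembl_id": "CHEMBL0000021", "canonical_smiles": "CCOC(=O)C1(CCN(C)CC1)c1ccccc1", "standard_type": "Ki", "standard_value": "410", "standard_units": "nM", "document_year": 2013},
    {"molecule_chembl_id": "CHEMBL0000022", "canonical_smiles": "CN1CCN(CC1)c1ccc(N)cc1", "standard_type": "Ki", "standard_value": "130", "standard_units": "nM", "document_year": 2018},
    {"molecule_chembl_id": "CHEMBL0000009", "canonical_smiles": "OC(=O)c1ccccc1O", "standard_type": "Ki", "standard_value": "9.1", "standard_units": "uM", "document_year": 2009},
    {"molecule_chembl_id": "CHEMBL0000010", "canonical_smiles": "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "standard_type": "Ki", "standard_value": null, "standard_units": "nM", "document_year": 2013},
    {"malformed": true}
  ]
}
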