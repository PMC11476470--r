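data_toy
loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_alt_id
_atom_site.label_comp_id
_atom_site.label_asym_id
_atom_site.label_entity_id
_atom_site.label_seq_id
_atom_site.pdbx_PDB_ins_code
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
_atom_site.occupancy
_atom_site.B_iso_or_equiv
_atom_site.auth_seq_id
_atom_site.auth_asym_id
_atom_site.pdbx_PDB_model_num
ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 90.00 1 A 1
ATOM 2 C CA . ALA A 1 1 ? 1.458 0.000 0.000 1.00 90.00 1 A 1
ATOM 3 C CA . GLY A 1 2 ? 2.000 3.800 0.000 1.00 85.00 2 A 1
ATOM 4 C CA . SER B 2 1 ? 5.000 1.000 2.000 1.00 70.00 1 B 1
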