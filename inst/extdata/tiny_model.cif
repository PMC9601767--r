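data_mini
#
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
_atom_site.pdbx_formal_charge
_atom_site.auth_seq_id
_atom_site.auth_comp_id
_atom_site.auth_asym_id
_atom_site.auth_atom_id
_atom_site.pdbx_PDB_model_num
ATOM 1  N N  . MET A 1 1 ? 10.000 10.000 10.000 1.00 90.00 ? 1 MET A N  1
ATOM 2  C CA . MET A 1 1 ? 11.400 10.000 10.000 1.00 90.00 ? 1 MET A CA 1
ATOM 3  C C  . MET A 1 1 ? 12.000 11.400 10.000 1.00 90.00 ? 1 MET A C  1
ATOM 4  O O  . MET A 1 1 ? 13.200 11.500 10.000 1.00 90.00 ? 1 MET A O  1
ATOM 5  N N  . LYS A 1 2 ? 11.300 12.500 10.000 1.00 50.00 ? 2 LYS A N  1
ATOM 6  C CA . LYS A 1 2 ? 11.800 13.800 10.000 1.00 50.00 ? 2 LYS A CA 1
ATOM 7  C C  . LYS A 1 2 ? 13.300 13.900 10.000 1.00 50.00 ? 2 LYS A C  1
ATOM 8  O O  . LYS A 1 2 ? 13.900 14.900 10.000 1.00 50.00 ? 2 LYS A O  1
ATOM 9  N N  . VAL A 1 3 ? 13.900 12.700 10.000 1.00 30.00 ? 3 VAL A N  1
ATOM 10 C CA . VAL A 1 3 ? 15.300 12.600 10.000 1.00 30.00 ? 3 VAL A CA 1
#
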