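data_synthetic_helix
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
ATOM 1 C CA . GLY A 1 1 ? 2.300 0.000 0.000 1.00 23.27 ? 1 GLY A CA 1
ATOM 2 C CA . GLY A 1 2 ? -0.399 2.265 1.500 1.00 26.18 ? 2 GLY A CA 1
ATOM 3 C CA . GLY A 1 3 ? -2.161 -0.787 3.000 1.00 28.41 ? 3 GLY A CA 1
ATOM 4 C CA . GLY A 1 4 ? 1.150 -1.992 4.500 1.00 29.72 ? 4 GLY A CA 1
ATOM 5 C CA . GLY A 1 5 ? 1.762 1.478 6.000 1.00 29.95 ? 5 GLY A CA 1
ATOM 6 C CA . GLY A 1 6 ? -1.762 1.478 7.500 1.00 29.09 ? 6 GLY A CA 1
ATOM 7 C CA . GLY A 1 7 ? -1.150 -1.992 9.000 1.00 27.23 ? 7 GLY A CA 1
ATOM 8 C CA . GLY A 1 8 ? 2.161 -0.787 10.500 1.00 24.57 ? 8 GLY A CA 1
ATOM 9 C CA . GLY A 1 9 ? 0.399 2.265 12.000 1.00 21.41 ? 9 GLY A CA 1
ATOM 10 C CA . GLY A 1 10 ? -2.300 0.000 13.500 1.00 18.09 ? 10 GLY A CA 1
ATOM 11 C CA . GLY A 1 11 ? 0.399 -2.265 15.000 1.00 14.99 ? 11 GLY A CA 1
ATOM 12 C CA . GLY A 1 12 ? 2.161 0.787 16.500 1.00 12.43 ? 12 GLY A CA 1
ATOM 13 C CA . GLY A 1 13 ? -1.150 1.992 18.000 1.00 10.71 ? 13 GLY A CA 1
ATOM 14 C CA . GLY A 1 14 ? -1.762 -1.478 19.500 1.00 10.01 ? 14 GLY A CA 1
ATOM 15 C CA . GLY A 1 15 ? 1.762 -1.478 21.000 1.00 10.41 ? 15 GLY A CA 1
ATOM 16 C CA . GLY A 1 16 ? 1.150 1.992 22.500 1.00 11.87 ? 16 GLY A CA 1
ATOM 17 C CA . GLY A 1 17 ? -2.161 0.787 24.000 1.00 14.22 ? 17 GLY A CA 1
ATOM 18 C CA . GLY A 1 18 ? -0.399 -2.265 25.500 1.00 17.21 ? 18 GLY A CA 1
ATOM 19 C CA . GLY A 1 19 ? 2.300 -0.000 27.000 1.00 20.50 ? 19 GLY A CA 1
ATOM 20 C CA . GLY A 1 20 ? -0.399 2.265 28.500 1.00 23.74 ? 20 GLY A CA 1
#
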