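data_SYN1
# synthetic mmCIF fixture: one Met (altloc pair on SD) and one Phe ring
# centered 4.5 A above SD; a second model shifted +20 in x
_entry.id SYN1
loop_
_entity.id
_entity.type
_entity.pdbx_ec
1 polymer 3.2.1.14
_refine.ls_d_res_high 1.85
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
ATOM 1  C CG  . MET A 1 10 ? 1.810  0.000  0.000  1.00 20.00 10 A 1
ATOM 2  S SD  A MET A 1 10 ? 0.000  0.000  0.000  0.60 21.00 10 A 1
ATOM 3  S SD  B MET A 1 10 ? 0.400  0.000  0.000  0.40 21.00 10 A 1
ATOM 4  C CE  . MET A 1 10 ? -0.311 1.763  0.000  1.00 22.00 10 A 1
ATOM 5  C CG  . PHE A 1 20 ? 0.000  1.390  4.500  1.00 15.00 20 A 1
ATOM 6  C CD1 . PHE A 1 20 ? -1.204 0.695  4.500  1.00 15.00 20 A 1
ATOM 7  C CE1 . PHE A 1 20 ? -1.204 -0.695 4.500  1.00 15.00 20 A 1
ATOM 8  C CZ  . PHE A 1 20 ? 0.000  -1.390 4.500  1.00 15.00 20 A 1
ATOM 9  C CE2 . PHE A 1 20 ? 1.204  -0.695 4.500  1.00 15.00 20 A 1
ATOM 10 C CD2 . PHE A 1 20 ? 1.204  0.695  4.500  1.00 15.00 20 A 1
ATOM 11 C CG  . MET A 1 10 ? 21.810 0.000  0.000  1.00 20.00 10 A 2
ATOM 12 S SD  . MET A 1 10 ? 20.000 0.000  0.000  1.00 21.00 10 A 2
ATOM 13 C CE  . MET A 1 10 ? 19.689 1.763  0.000  1.00 22.00 10 A 2
#
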