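name: carbinolamine_quartet
require_ligand_contact: yes
ligand_sites:
- site_id: nuc_c
  atom: C1
  role: covalent_attachment
  aux:
  - O1
  - C2
- site_id: oxy_acc
  atom: O1
  role: acceptor
  aux:
  - C1
- site_id: oh_don
  atom: O3
  role: donor
  aux:
  - H3
- site_id: oh_acc
  atom: O3
  role: acceptor
  aux:
  - C3
groups:
- label: K1
  fg: primary_amine
- label: Y1
  fg: phenol
- label: Y2
  fg: phenol
- label: N1
  fg: carboxamide
edges:
- id: e_cov
  kind: covalent
  a:
    ligand: nuc_c
  b:
    group: K1
- id: e_y1_lig
  kind: hbond
  a:
    group: Y1
    role: donor
  b:
    ligand: oxy_acc
- id: e_k1_y1
  kind: hbond
  a:
    group: K1
    role: donor
  b:
    group: Y1
    role: acceptor
- id: e_n1_lig
  kind: hbond
  a:
    group: N1
    role: donor
  b:
    ligand: oh_acc
- id: e_y2_lig
  kind: hbond
  a:
    ligand: oh_don
  b:
    group: Y2
    role: acceptor
- id: e_n1_y2
  kind: hbond
  a:
    group: N1
    role: donor
  b:
    group: Y2
    role: acceptor
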