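layers:
- name: omimDGN
  file: omim_dgn.tsv
  format: edge_list
  directed: yes
- name: PathGN
  file: pathways.gmt
  format: gmt
- name: PPIN
  file: ppi.tsv
  format: edge_list
alpha: 0.7
total_jump: 0.5
seeds:
- gene:CHCHD6
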