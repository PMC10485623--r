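allowed:
- - internal_protein
  - internal_protein
  - same_cell
- - internal_protein
  - membrane_protein
  - same_cell
- - internal_protein
  - gene
  - same_cell
- - membrane_protein
  - membrane_protein
  - adjacent_cell
self_edges: no
and_pairs: yes
prespecified:
- ci -> CI +
- CIA&SLP -> wg +
- CIA&wg -> wg +
- en -> EN +
- hh -> HH +
- HH@adj -> SMO +
- ptc -> PTC +
- PTC -> PTC +
- PTC -> SMO -
- SLP&wg -> wg +
- wg -> WG +
forbidden: []
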