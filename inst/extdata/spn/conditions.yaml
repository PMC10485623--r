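species:
- wg
- en
- hh
- ptc
- ci
- SLP
- EN
- CI
- CIR
- CIA
- WG
- PTC
- SMO
- PH
- HH
- wg@1
- en@1
- hh@1
- ptc@1
- ci@1
- SLP@1
- EN@1
- CI@1
- CIR@1
- CIA@1
- WG@1
- PTC@1
- SMO@1
- PH@1
- HH@1
- wg@2
- en@2
- hh@2
- ptc@2
- ci@2
- SLP@2
- EN@2
- CI@2
- CIR@2
- CIA@2
- WG@2
- PTC@2
- SMO@2
- PH@2
- HH@2
- wg@3
- en@3
- hh@3
- ptc@3
- ci@3
- SLP@3
- EN@3
- CI@3
- CIR@3
- CIA@3
- WG@3
- PTC@3
- SMO@3
- PH@3
- HH@3
conditions:
- name: wild_type
  knockouts: []
  initial_states:
  - '011000100000001000110010001000000111010001000100111010011000'
  reference:
  - state: '011000100000101000110010101110000011011001000100111010111110'
    count: 1
- name: wg_knockout
  knockouts:
  - wg
  initial_states:
  - '011000100000001000110010001000000111010001000000111010001000'
  reference:
  - state: '000010011001000000010011001000000011011001000000011011001000'
    count: 1
- name: hh_knockout
  knockouts:
  - hh
  initial_states:
  - '010000100000000000110010001000000111010001000100111010011000'
  reference:
  - state: '000010011001000000010011001000000011011001000000011011001000'
    count: 1
- name: en_knockout
  knockouts:
  - en
  initial_states:
  - '001000000000001000110010001000000111010001000100111010011000'
  reference:
  - state: '000010011001000000010011001000000011011001000000011011001000'
    count: 1
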