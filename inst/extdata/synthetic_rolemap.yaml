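roles:
  HZ: {chain: A, resno: 46, name: HZ}
  CA: {chain: A, resno: 500, name: CA}
  H99: {chain: A, resno: 500, name: H99}
  C50: {chain: A, resno: 500, name: C50}
  N99: {chain: A, resno: 500, name: N99}
  C80: {chain: A, resno: 500, name: C80}
  OE1: {chain: A, resno: 246, name: OE1}
  H1: {chain: A, resno: 500, name: H1}
  DISTAL_CA: {chain: A, resno: 500, name: CAD}
  LYS_NZ: {chain: A, resno: 46, name: NZ}
  MC1_ANCHOR: {chain: A, resno: 500, name: O3}
  MC2_ANCHOR: {chain: A, resno: 65, name: OD1}
  MC3_ANCHOR: {chain: A, resno: 71, name: OE1}
  PLP_ANCHOR_SET:
    - {chain: A, resno: 500, name: C50}
    - {chain: A, resno: 500, name: C3}
    - {chain: A, resno: 500, name: O3}
    - {chain: A, resno: 500, name: N1}
    - {chain: A, resno: 500, name: H1}
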