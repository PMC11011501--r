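# G3P binding-mode profile for GPAT4.
# Distances are measured from the phosphorus atom of G3P to the anchor
# atom (NZ for Lys, CZ for Arg, NE2 for His).  All cutoffs 5 A except the
# catalytic-histidine condition of mode 1 (11 A).  Precedence: lower rank
# is tested first.  Mode 6 is the dummy fallback.
modes:
  - id: 1
    precedence: 1
    conditions:
      - {residue: R427, atom: CZ, cutoff: 5.0}
      - {residue: H248, atom: NE2, cutoff: 11.0}
  - id: 2
    precedence: 2
    conditions:
      - {residue: K296, atom: NZ, cutoff: 5.0}
      - {residue: R292, atom: CZ, cutoff: 5.0}
  - id: 3
    precedence: 5
    conditions:
      - {residue: R427, atom: CZ, cutoff: 5.0}
      - {residue: K426, atom: NZ, cutoff: 5.0}
  - id: 4
    precedence: 3
    conditions:
      - {residue: R148, atom: CZ, cutoff: 5.0}
      - {residue: R374, atom: CZ, cutoff: 5.0}
  - id: 5
    precedence: 4
    conditions:
      - {residue: R427, atom: CZ, cutoff: 5.0}
      - {residue: K365, atom: NZ, cutoff: 5.0}
  - id: 6
    precedence: 6
    fallback: true
    conditions: []
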