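# Example selection config for rat CPR, 1AMO author numbering.
# USER-EDITABLE: the split between the FMN domain and the FAD domain
# (customarily taken to include the connecting domain) is an analysis
# choice, not something the package fixes.  The residue ranges below are
# approximate literature boundaries - adjust them to your construct,
# numbering and hinge assignment before use.  No test depends on them.
selections:
  fmn_domain:
    chain_id: A
    residue_ranges: [[77, 228]]
  fad_domain:            # includes the hinge and connecting domain
    chain_id: A
    residue_ranges: [[229, 678]]
  fad_ring:              # alloxazine ring of the FAD cofactor
    residue_names: [FAD]
    atom_names: [N1, C2, O2, N3, C4, O4, C4A, N5, C5A, C6, C7, C8, C9, C9A, N10]
  fmn_ring:              # alloxazine ring of the FMN cofactor
    residue_names: [FMN]
    atom_names: [N1, C2, O2, N3, C4, O4, C4A, N5, C5A, C6, C7, C8, C9, C9A, N10]
  heme:                  # heme of the partner protein in a complex reference
    residue_names: [HEM]
temperature: 310
bins: 50
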