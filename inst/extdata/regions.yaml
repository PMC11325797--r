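# Default Galpha-S switch-region definitions (author/PDB residue numbering,
# inclusive ranges). Configuration data: edit or replace per system.
regions:
  switch_I: [197, 207]
  switch_II: [219, 236]
  switch_III: [254, 270]
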