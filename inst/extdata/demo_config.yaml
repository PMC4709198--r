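# Demonstration run: a small synthetic tetramer-in-bilayer system with
# one planted head contact, analysed end to end.
synthetic:
  n_frames: 60
  n_ligands: 3
  n_lipids: 10
  seed: 11
  planted_contacts:
  - chain: A
    resid: 312
    ligand: 1
    part: head
    intervals:
    - [5.0, 45.0]
criteria:
  contact_cutoff: 3.5
  contact_threshold_ns: 20
  residency_cutoff: 3.5
  density_voxel: 2.0
  density_iso: 0.27
output_dir: amphitraj_demo
seed: 11
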