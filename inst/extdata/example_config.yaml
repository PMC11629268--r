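# Example run configuration for gpcrtraj::run_pipeline().
# Paths are relative to where you invoke the pipeline.
systems:
  - label: Gq
    structure: Gq/complex.pdb        # PDB or GRO topology
    trajectories:                     # one multi-model PDB or DCD per replica
      - Gq/traj_rep1.pdb
      - Gq/traj_rep2.pdb
    annotation: Gq/annotation.tsv     # chain, resnum, icode, generic_number, substructure
    dt: 1                             # ns per frame when the file has no times
    chain_roles: {A: receptor, B: partner, M: membrane, W: water, I: ion}
  - label: Gi
    structure: Gi/complex.pdb
    trajectories: [Gi/traj_rep1.pdb, Gi/traj_rep2.pdb]
    annotation: Gi/annotation.tsv
    dt: 1
    chain_roles: {A: receptor, B: partner, M: membrane, W: water, I: ion}

comparisons:
  - [Gq, Gi]                          # torsion-ensemble JSD comparisons

discard: auto                         # or a fixed cut in ns, e.g. 200
window: 50                            # ns, stationarity window
k: 2                                  # tolerance in noise SDs

thresholds:
  presence: 50                        # % presence for additional interface residues
  occupancy: 30                       # % average occupancy filter for contacts
  occupancy_display: 50               # % threshold for the contact matrix
  jsd_display: 0.6                    # JSD display threshold
  min_dsasa: 0.05                     # nm^2, membership exclusion filter
  min_norm: 10                        # %, normalised delta-SASA exclusion filter
  water_radius: 8                     # Angstrom, hydration shell

sasa:
  probe: 0.14                         # nm
  n_points: 960                       # spiral points per atom

jsd_bins: 36
stride: 1
seed: 1
out_dir: results
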