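# Demo configuration for the fully synthetic phquench pipeline.
# All randomness derives from the single master seed below; stage seeds are
# obtained by fixed offsets, so a rerun is byte-identical.
seed: 20240
temperature_K: 300

titration:
  pH: [3, 4, 5, 6, 7, 8]
  n_frames: 2000        # frames per replica per pH (dt 100 ps -> 200 ns)
  n_replicas: 2
  block_frames: 100     # 10 ns blocks for the blocked bootstrap
  n_boot: 200

microstates:
  triad: [E114, E227, E233]
  lag_frames: 100       # 10 ns lag
  top_k: 4

landscape:
  pms: [DDP, PDD, DPP, PDP]   # microstates carried to enhanced sampling
  n_frames: 400
  n_replicas: 2
  ar_phi: 0.9
  feature_sd: 1.0
  burn_in_ps: 2000
  lag_frames: 20
  n_dims: 2
  min_cluster_frac: 0.02
  bins: 40
  n_per_cluster: 30

structure:
  n_frames: 200
  spread: 0.6
  coverage: 0.40

coupling:
  n_frames: 30
  rescale: 3.7

energetics:
  n_samples: 30
  E_LE_mean: 15600
  E_CT_mean: 20700
  E_LE_sd: 700
  E_CT_sd: 1700
  n_pool: 8
  k_intr: 2.5e+8         # (4 ns)^-1
  k_rec: 1.0e+11         # (10 ps)^-1
  lambda_sets:
    membrane_estimate:
      lambda: 4500
      deltaG: -1200
    screened_estimate:
      lambda: 2500
      deltaG: -400
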