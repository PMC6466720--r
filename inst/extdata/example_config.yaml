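# Example pipeline configuration for a scaled-down family-tank trial.
# Any sim_config() field may appear under `simulate`; unset fields keep
# their defaults (the full 23-family, 50-fish, 12-day design).
simulate:
  n_families: 8
  n_fish_per_tank: 25
  n_snps: 1000
  seed: 1
derive:
  rg_low: 6.4
  rg_high: 49
grm:
  maf_min: 0.01
  call_rate_min: 0.9
fit:
  pairs:
    - traits: [fcr, rg_bar]
      level: tank
    - traits: [wg, amn]
      level: individual
regress:
  candidates: [fi, rg_bar, wg_bar, amc_bar, amn_bar, alc_bar, aln_bar, aac_bar]
  interactions: false
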