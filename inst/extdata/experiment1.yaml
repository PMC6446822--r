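# First selection experiment: three release treatments (control,
# everywhere 4:1, whack-a-mole 12:1) are run automatically by cmd_run;
# the strategy block sets the release ratios shared by the treatments.
experiment: experiment1
n_subpops: 3
n_replicates: 3
founder_pupae: 200
founder_r_freq: 0.075
generations: 4
bioassay_n: 100
bioassay_fraction: 0.10
dispersal_fraction: 0.10
release_start_generation: 1
master_seed: 20181124
strategy:
  mode: everywhere
  base_ratio: 4
  whack_multiplier: 3
regime:
  mode: homogeneous
  refuge: 0.10
selection:
  toxin_survival: [0, 0, 1]
  refuge_survival: 0.8
  fitness_cost_r: 0
  tetracycline: false
demography:
  eggs_per_female: 150
  capacity_refuge: 2000
  capacity_toxin: 2000
  eggs_placed_max: 2500
  sex_ratio: 0.5
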