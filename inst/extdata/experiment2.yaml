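# Second selection experiment: release strategy (everywhere / whack-a-mole)
# crossed with selection regime (homogeneous 12% refuge / heterogeneous
# 5-10-20% refuges permuted each generation); 150-larva bioassays.
experiment: experiment2
n_subpops: 3
n_replicates: 3
founder_pupae: 200
founder_r_freq: 0.075
generations: 4
bioassay_n: 150
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
  refuge: 0.12
  heterogeneous_refuges: [0.05, 0.10, 0.20]
selection:
  toxin_survival: [0, 0, 1]
  refuge_survival: 0.8
demography:
  eggs_per_female: 150
  capacity_refuge: 2000
  capacity_toxin: 2000
  eggs_placed_max: 2500
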