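# Glycerol-like serial-passage configuration: 200 ml minimal-medium flasks
# grown to OD600 ~0.7 (about 1.1e10 cells at 7.87e+10 cells/L/OD) from
# log-uniform inocula of 2.5e4-1.2e6 cells, ~14-19 generations per flask.
mu_per_division: 3.0e-05
mutagen_multiplier: 1
effect_size_mean: 0.03
gr_initial: 0.25
gr_cap: 0.64
transfer_count_range: [2.5e+04, 1.2e+06]
final_od_range: [0.6, 0.8]
volume: 0.2
conversion: 7.87e+10
max_flasks: 60
window: 10
rel_tol: 0.05
seed: 1
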