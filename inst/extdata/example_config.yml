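# Example end-to-end run configuration (see read_run_config / run_end_to_end).
# A run is reproducible from this file plus the seed alone.
n_per_group: 8
groups: [vehicle, vehicle_1nmpp1, tki, tki_bdnf]
base_seed: 1
nmj_n_per_class: 5
nmj_n_animals: 4
nmj_n_slices: 8
threshold: otsu
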