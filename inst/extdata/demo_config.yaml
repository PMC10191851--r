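# Demo configuration: small sizes so the full pipeline completes in about a
# minute. Any key omitted here falls back to the package default and every
# parameter actually used is echoed into report.json.
seed: 42
stages: [simulate, ecog, decode, connect, spectra, mea, stats]
ecog:
  n_participants: 4
  n_channels: 8
  n_trials_per_condition: 8
  tumour_amplitude_ratio: 2
  condition_effect_size: 2
connectivity:
  n_voxels_per_hemisphere: 60
  n_lesion_voxels: 10
  lesion_coupling_boost: 3
mea:
  n_wells: 2
  duration: 300
  n_network_bursts: 10
stats:
  cohort_n_per_group: 120
  cohort_medians_weeks: [71, 123]
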