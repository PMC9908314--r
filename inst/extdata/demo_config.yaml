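# Demo configuration for the synthetic TIPM pipeline (tipm run-all).
# Omitted entries fall back to default_run_config().
seed: 7
population:
  n_cells: 70
  cells_per_fish: 7
  slope_ipsi_mean: 0.07     # delta-F/F per degree, measured-slope units
  slope_ipsi_sd: 0.06
  slope_contra_mean: 0.02
  slope_contra_sd: 0.02
  phasic_sd: 0.35           # half-normal SD of per-event phasic peaks
  plateau_fraction: 0.5
  noise_sd: 0.35            # fraction of baseline F per sampled volume
  utricle_scale: 1.0        # 0.1 emulates utricle-null larvae
stimulus:
  step_magnitudes: [10, 20, 30]
  baseline_s: 10
  hold_s: 15
  response_s: 10
  trials_per_magnitude: 3
  repeats_per_trial: 2
  sample_rate_hz: 2.2
development:
  age1_dpf: 4
  age2_dpf: 7
  p_increase_ipsi: 0.2
  p_decrease_ipsi: 0.043
  increase_amount: 0.15        # ipsi slope change for increasing cells
  decrease_amount: 0.05
  contra_tuned_fraction: 0.343 # top contra-tuned third of the population
  p_decrease_contra_tuned: 0.458
  p_increase_contra_nontuned: 0.174
  contra_increase_amount: 0.05
longitudinal:
  n_shuffles: 1000
qc:
  frame_shift_px: [3, -2]
  frame_size: 64
  pixel_size_um: 1.0
  mount_dz_um: 7.2
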