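# Example pipeline configuration. Any key omitted here falls back to the
# package default; unknown keys are rejected.
polynomial_order: 12          # WASSR fit order
interpolation_resolution_ppm: 0.01
analysis_offset_ppm: 3.5      # amide resonance
max_shift_ppm: 0.5            # |B0| validity bound
alpha: 0.05
noise_sd: 0.005               # phantom noise, fraction of S0
between_subject_sd: 0.0025    # cohort amide-amplitude jitter
n_per_group: 7
groups: [CTRL, LPS05, LPS10]
grid_shape: [32, 32]
b0_amplitude_ppm: 0.15
seed: 1
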