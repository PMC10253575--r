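# Default study configuration. Marginal distributions of the four
# stiffness measures are built into cohort_spec() and equal the published
# two-group values; this file controls cohort size, panel mode and the
# waveform pipeline settings.
cohort:
  n_patients: 35
  n_controls: 18
# A: measured panel drawn directly from the group marginals (statistics).
# B: measured PWV re-estimated from simulated propagating waveforms.
panel_mode: A
calibrate_copula: true
n_mc_calibration: 20000
waveform:
  n_planes: 40
  snr_db: 20
  effective_dt_s: 0.034
  n_phases: 50
write_flow_curves: false
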