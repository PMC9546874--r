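# Calibrated default parameters for the commitment-circuit generator.
#
# The `transcribed` block holds quantities on the reporter scale that the
# underlying study reports directly: the cross-talk coefficient of the CDK2
# reporter on the CDK4/6 reporter, the CDK2 activity near which commitment
# becomes CDK4/6-independent, the earliest CDK4/6 activation onset after
# mitogen stimulation, the 12-min sampling interval, the 4-5 h lag between
# mitogen withdrawal and CDK4/6 inactivation, and the ~40% of
# CDK4/6-activating cells without CDK2 activation at the 14-h fixation.
# The onset-distribution scale is not stored: it is solved at load time so
# that the generative cohort reproduces `frac_no_cdk2_at_horizon` exactly
# (see calib_paper_params()).
#
# The `kinetics` block holds free phenomenological constants chosen once to
# reproduce the qualitative circuit behaviour (gradual ~5-h CDK2 rise after
# CDK4/6-on, saturating plateau near 2 reporter units, reversal to baseline
# within hours of rapid CDK4/6 inhibition in uncommitted cells).
transcribed:
  crosstalk_rho: 0.35
  theta_commit: 1.0
  onset_min: 3.0
  dt: 0.2
  horizon: 14.0
  withdrawal_delay_range: [4.0, 5.0]
  frac_no_cdk2_at_horizon: 0.40
  select_gate: 0.6
kinetics:
  p_active: 0.6
  a46_max: 1.5
  rise_tau: 1.0
  theta_rb: 0.3
  e2f_rate: 0.25
  e2f_decay: 0.25
  cdk2_rate: 0.12
  cdk2_fb: 0.75
  cdk2_decay: 0.25
  a2_baseline: 0.1
  a2_max: 2.8
  theta_on2: 0.6
  theta_apc: 1.2
  degron_rate: 1.0
  noise_sd: 0.05
  mrna_base: 2.0
  mrna_per_e2f: 30.0
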