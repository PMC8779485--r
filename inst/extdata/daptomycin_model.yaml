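# Default daptomycin model definition (bone and joint infection adults).
# np_moments: summary moments of the nonparametric population model
#   (micro-constant parameterization; V1 standardized to 70 kg,
#   Ke = Ks * (CLCR/100) + Ki).
# parametric: clearance-parameterized prior for the MAP engine; the CLCR
#   effect form is declared explicitly (linear_renal: renal/non-renal split).
np_moments:
  mean: {v1_std: 6.90, ks: 0.050, ki: 0.060, kcp: 0.693, kpc: 0.667}
  cv:   {v1_std: 0.394, ks: 0.896, ki: 0.832, kcp: 1.180, kpc: 0.977}
parametric:
  tv_cl: 0.759
  tv_v1: 6.90
  tv_q: 4.7817
  tv_v2: 7.16897
  omega: {cl: 0.65, v1: 0.38, q: 0.95, v2: 1.1}
  clcr_form: linear_renal
  f_renal: 0.4545
  male_cl_factor: 1.0
  wt_exp_q: 1.0
  wt_exp_v2: 1.0
error:
  c0: 0.5
  c1: 0.1
  lloq: 2
targets:
  auc_target: 666
  cmin_limit: 24.3
template:
  interval_h: 24
  infusion_duration_h: 0.5
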