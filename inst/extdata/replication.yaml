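# Replication fixture: the study's design constants.
# Group sizes, demographics, deficit-class margins and aggregates, and LPE
# prevalence targets follow the published sample (CD n=542 / TDC n=710,
# ages 9-18, recognition/learning/regulation deficit margins 23/13/18%,
# no-deficit 56.3%, pervasive cell 1%, LPE 43.7% CD / 18.3% TDC). The three
# pairwise-overlap cells are package choices constrained by those aggregates;
# latent/measurement parameters are package design choices (see the methods
# vignette).
name: replication
n_cd: 542
n_tdc: 710
seed: 1
age_range: [9.0, 19.0]
bracket_edges: [9.0, 13.0, 16.0, 19.0]
sex_ratio_by_group: {cd: 0.585, tdc: 0.675}
iq_mean_sd_by_group:
  cd: [94.9, 12.4]
  tdc: [103.5, 12.2]
ses_mean_sd_by_group:
  cd: [-0.29, 0.93]
  tdc: [0.28, 1.03]
deficit_class_probs_cd:
  none: 0.563
  rec: 0.155
  lrn: 0.077
  reg: 0.112
  rec+lrn: 0.025
  rec+reg: 0.040
  lrn+reg: 0.018
  rec+lrn+reg: 0.010
deficit_class_probs_tdc:
  none: 0.729
  rec: 0.081
  lrn: 0.081
  reg: 0.081
  rec+lrn: 0.009
  rec+reg: 0.009
  lrn+reg: 0.009
  rec+lrn+reg: 0.001
domain_corr: 0.3
deficit_shift: 1.8
group_shift: -0.15
covariate_betas: {age: 0.08, iq: 0.015, sex_male: -0.10}
noise_sd: 0.5
lpe_target: {cd: 0.437, tdc: 0.183}
cd_symptom_mean: 5.45
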