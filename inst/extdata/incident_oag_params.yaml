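cohort:
  n_total: 1986
  target_incidence: 0.033736153071501
  female_frac_case: 0.73
  female_frac_control: 0.57
  missing_rate: 0.0
covariates:
- name: age
  case_mean: 68.900000000000006
  case_sd: 7.9
  control_mean: 63.799999999999997
  control_sd: 8.300000000000001
  lower: 0.0
  upper: .inf
- name: iop
  case_mean: 17.600000000000001
  case_sd: 2.8
  control_mean: 15.9
  control_sd: 2.6
  lower: 0.0
  upper: .inf
- name: vcdr
  case_mean: 0.53
  case_sd: 0.11
  control_mean: 0.42
  control_sd: 0.12
  lower: 0.0
  upper: 1.0
- name: dd
  case_mean: 1.52
  case_sd: 0.18
  control_mean: 1.51
  control_sd: 0.17
  lower: 0.0
  upper: .inf
- name: sbp
  case_mean: 151.599999999999994
  case_sd: 21.199999999999999
  control_mean: 144.0
  control_sd: 20.399999999999999
  lower: 0.0
  upper: .inf
- name: dbp
  case_mean: 85.700000000000003
  case_sd: 9.5
  control_mean: 83.400000000000006
  control_sd: 9.6
  lower: 0.0
  upper: .inf
snps:
- snp_id: rs4656461
  chromosome: '1'
  position_bp: 163953829
  risk_allele: G
  other_allele: A
  locus: TMCO1
  case_freq: 0.187
  control_freq: 0.116
- snp_id: rs4236601
  chromosome: '7'
  position_bp: 115949965
  risk_allele: A
  other_allele: G
  locus: CAV1/CAV2
  case_freq: 0.313
  control_freq: 0.268
- snp_id: rs1521774
  chromosome: '8'
  position_bp: 106048166
  risk_allele: G
  other_allele: A
  locus: 8q22
  case_freq: 0.366
  control_freq: 0.324
- snp_id: rs1063192
  chromosome: '9'
  position_bp: 21993367
  risk_allele: A
  other_allele: G
  locus: 9p21
  case_freq: 0.642
  control_freq: 0.549
- snp_id: rs1412829
  chromosome: '9'
  position_bp: 22033926
  risk_allele: A
  other_allele: G
  locus: 9p21
  case_freq: 0.687
  control_freq: 0.568
- snp_id: rs4977756
  chromosome: '9'
  position_bp: 22058652
  risk_allele: A
  other_allele: G
  locus: 9p21
  case_freq: 0.687
  control_freq: 0.591
- snp_id: rs10483727
  chromosome: '14'
  position_bp: 60142628
  risk_allele: A
  other_allele: G
  locus: SIX1/SIX6
  case_freq: 0.508
  control_freq: 0.384
model:
  intercept: -16.221
  vcdr_scale: 10.0
  betas:
    sex: 0.93
    age: 0.064
    iop: 0.217
    vcdr: 0.827
    dd: -1.803
    sbp: -0.005
    dbp: 0.021
    rs4656461: 0.608
    rs1412829: 0.439
    rs10483727: 0.525
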