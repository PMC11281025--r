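# Shipped constants for the six-metal wetland water assessment.
# Units: concentrations and thresholds ug/L; RfD ug/kg/d; SF (ug/kg/d)^-1;
# Kp cm/h. A "~" entry means the toxicity value is not defined for that
# metal/route, which excludes the metal from the corresponding assessment.
metals:
  Hg: {class2_threshold: 0.05, detection_limit: 0.04, kp: 1.0e-3, rfd_ing: 0.3, rfd_derm: 0.024, sf_ing: ~, sf_derm: ~}
  As: {class2_threshold: 50.0, detection_limit: 0.30, kp: 1.0e-3, rfd_ing: 0.3, rfd_derm: 0.123, sf_ing: 1.5e-3, sf_derm: 3.66e-3}
  Cu: {class2_threshold: 1000.0, detection_limit: 0.08, kp: 1.0e-3, rfd_ing: 40.0, rfd_derm: 12.0, sf_ing: ~, sf_derm: ~}
  Zn: {class2_threshold: 1000.0, detection_limit: 0.67, kp: 6.0e-4, rfd_ing: 300.0, rfd_derm: 60.0, sf_ing: ~, sf_derm: ~}
  Pb: {class2_threshold: 10.0, detection_limit: 0.09, kp: 1.0e-4, rfd_ing: 1.4, rfd_derm: 0.42, sf_ing: ~, sf_derm: ~}
  Cd: {class2_threshold: 5.0, detection_limit: 0.05, kp: 1.0e-3, rfd_ing: 0.5, rfd_derm: 0.005, sf_ing: 6.1e-3, sf_derm: 3.8e-4}
exposure:
  children:
    ir: {family: normal, mean: 1.25, sd: 0.3}          # L/day
    ef: {family: triangular, min: 180.0, mode: 350.0, max: 360.0}  # days/year
    ed: 2.5                                            # years
    bw: {family: normal, mean: 20.0, sd: 0.15}         # kg
    at_noncancer: 912.5                                # days
    at_cancer: 25550.0                                 # days
    sa: 7422.0                                         # cm^2
    t_event: 0.58                                      # h/event
    ev: 1.0                                            # events/day
  adults:
    ir: {family: normal, mean: 1.95, sd: 0.3}
    ef: {family: triangular, min: 180.0, mode: 350.0, max: 360.0}
    ed: 26.0
    bw: {family: normal, mean: 70.0, sd: 0.15}
    at_noncancer: 9490.0
    at_cancer: 25550.0
    sa: 18182.0
    t_event: 1.0
    ev: 1.0
schemes:
  contamination:
    cuts: [0.7, 1.0, 2.0, 3.0]
    labels: [no contamination, slight contamination, light contamination, moderate contamination, high contamination]
    boundary: lower   # a value exactly on a cut joins the less severe class
  cancer_risk:
    cuts: [1.0e-6, 1.0e-4, 1.0e-3, 0.1]
    labels: [very low risk, low risk, moderate risk, high risk, extremely high risk]
    boundary: upper   # half-open [cut, next): a value on a cut joins the more severe class
# Published group-level summary statistics of the study's 36 water samples
# (concentrations ug/L); these define the synthetic generator's targets.
groups:
  urban:
    n_samples: 20
    stats:
      Hg: {mean: 0.16, sd: 0.21, min: 0.04, max: 0.88}
      As: {mean: 2.70, sd: 1.80, min: 0.50, max: 8.30}
      Cu: {mean: 37.76, sd: 20.46, min: 1.48, max: 73.0}
      Zn: {mean: 93.18, sd: 54.33, min: 7.44, max: 298.0}
      Pb: {mean: 1.20, sd: 0.86, min: 0.10, max: 3.53}
      Cd: {mean: 0.09, sd: 0.06, min: 0.05, max: 0.34}
  rural:
    n_samples: 16
    stats:
      Hg: {mean: 0.25, sd: 0.31, min: 0.04, max: 1.13}
      As: {mean: 4.15, sd: 1.79, min: 2.10, max: 7.60}
      Cu: {mean: 63.29, sd: 49.42, min: 1.22, max: 232.0}
      Zn: {mean: 175.65, sd: 71.0, min: 78.60, max: 344.0}
      Pb: {mean: 2.18, sd: 0.89, min: 0.97, max: 3.70}
      Cd: {mean: 0.14, sd: 0.06, min: 0.05, max: 0.27}
# Published group-average single-factor pollution indices (dimensionless),
# kept for validation and reporting against the study's own tables.
published_indices:
  urban: {Hg: 3.21, As: 0.05, Cu: 0.04, Zn: 0.09, Pb: 0.12, Cd: 0.02}
  rural: {Hg: 4.98, As: 0.08, Cu: 0.06, Zn: 0.18, Pb: 0.22, Cd: 0.03}
# Field ranges for pass-through water-quality metadata.
ph_range: [6.84, 8.36]
ec_range: [423.0, 5820.0]
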