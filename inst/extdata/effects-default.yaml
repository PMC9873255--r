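# Default effect model for the synthetic tenotomy cohort (version 1).
#
# Paper-inspired generator choices: they emulate the qualitative structure
# of tenotomy-induced rotator-cuff atrophy (fiber-length loss dominating in
# both sexes, type-2b CSA loss confined to males, larger fiber-number loss
# in females, sex-specific sham baselines) and are calibrated so that the
# male W2/W8 log-decomposition CSA share sits near 27% and the female
# fiber-number share near 35%. They are NOT measured values from any
# dataset; users wanting closer realism should fit baselines and ratios to
# their own measurements.
version: 1
density: 1.056        # g/cm^3, standard mammalian muscle density
noise_cv: 0.05        # lognormal measurement noise CV
area_fractions:       # fixed fiber-type area fractions (supraspinatus-like)
  "1": 0.02
  "2a": 0.26
  "2x": 0.33
  "2b": 0.39
architecture:
  fl_to_ml: 0.38      # fiber-length / muscle-length ratio (placeholder)
  pennation_deg: 0.0  # pennation angle (placeholder)
specific_tension:     # N/cm^2, used to synthesize peak tetanic force
  SHM: 22.0
  TEN: 14.0
baseline:
  - {sex: M, body_mass_g: 30.0, ta_mass_mg: 48.0, fiber_number: 3500,
     csa_1: 1400.0, csa_2a: 1700.0, csa_2x: 2100.0, csa_2b: 2600.0,
     muscle_length_cm: 1.30, is_scale: 1.6}
  - {sex: F, body_mass_g: 24.0, ta_mass_mg: 40.0, fiber_number: 3000,
     csa_1: 1200.0, csa_2a: 1500.0, csa_2x: 1800.0, csa_2b: 2000.0,
     muscle_length_cm: 1.20, is_scale: 1.6}
effects:
  - {sex: M, timepoint: W1, fn_ratio: 0.99, fl_ratio: 0.95,
     csa_ratio_1: 1.0, csa_ratio_2a: 1.0, csa_ratio_2x: 1.0, csa_ratio_2b: 0.97}
  - {sex: M, timepoint: W2, fn_ratio: 0.9378, fl_ratio: 0.8218,
     csa_ratio_1: 1.0, csa_ratio_2a: 1.0, csa_ratio_2x: 1.0, csa_ratio_2b: 0.7646}
  - {sex: M, timepoint: W8, fn_ratio: 0.8980, fl_ratio: 0.7198,
     csa_ratio_1: 1.0, csa_ratio_2a: 1.0, csa_ratio_2x: 1.0, csa_ratio_2b: 0.6177}
  - {sex: F, timepoint: W1, fn_ratio: 0.98, fl_ratio: 0.96,
     csa_ratio_1: 1.0, csa_ratio_2a: 1.0, csa_ratio_2x: 1.0, csa_ratio_2b: 1.0}
  - {sex: F, timepoint: W2, fn_ratio: 0.9167, fl_ratio: 0.8509,
     csa_ratio_1: 1.0, csa_ratio_2a: 1.0, csa_ratio_2x: 1.0, csa_ratio_2b: 1.0}
  - {sex: F, timepoint: W8, fn_ratio: 0.8737, fl_ratio: 0.7783,
     csa_ratio_1: 1.0, csa_ratio_2a: 1.0, csa_ratio_2x: 1.0, csa_ratio_2b: 1.0}
genotype:
  - {genotype: WT,  csa_scale: 1.00, ten_fl_scale: 1.00}
  - {genotype: MKD, csa_scale: 1.05, ten_fl_scale: 1.00}
  - {genotype: MCA, csa_scale: 1.00, ten_fl_scale: 0.97}
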