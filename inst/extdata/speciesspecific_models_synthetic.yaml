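# SYNTHETIC STAND-INS for five species-specific Sequoia sempervirens
# allometries (Parks; Fujimori; Sillett et al. crown-mapping model on DTB &
# fDBH; Sillett et al. ground-measurement model on DTB & H; Kizha & Han
# destructive-harvest DBH model). The exact published coefficient values for
# these models live in sources not redistributable here, so the entries
# below are synthetic: the functional forms and predictor sets follow the
# originals, while the coefficients were chosen once from geometric
# form-factor reasoning (stem volume ~ form factor x basal area x height,
# basic density 330 kg m^-3) to give realistic magnitudes for 10-90 m
# redwood-type stems. They are suitable for exercising and testing the
# pipeline, not for operational biomass estimation.
models:
  parks:
    form: power_product
    predictors: [DBH, H]
    predictor_units: m
    response: volume_m3
    coefficients:
      beta0: 0.28
      beta1: 1.95
      beta2: 1.0
    correction_factor: 1.0
    wood_density_kg_m3: 330
    source: "synthetic stand-in (Parks-style DBH,H volume model)"
  fujimori:
    form: power_product
    predictors: [DBH, H]
    predictor_units: m
    response: volume_m3
    coefficients:
      beta0: 0.33
      beta1: 2.05
      beta2: 0.95
    correction_factor: 1.0
    wood_density_kg_m3: 330
    source: "synthetic stand-in (Fujimori-style DBH,H volume model)"
  sillett2015:
    form: power_product
    predictors: [DTB, fDBH]
    predictor_units: m
    response: volume_m3
    coefficients:
      beta0: 15.0
      beta1: 1.25
      beta2: 1.25
    correction_factor: 1.0
    wood_density_kg_m3: 330
    source: "synthetic stand-in (crown-mapping-style DTB,fDBH volume model)"
  sillett2019:
    form: power_product
    predictors: [DTB, H]
    predictor_units: m
    response: volume_m3
    coefficients:
      beta0: 0.30
      beta1: 2.1
      beta2: 1.0
    correction_factor: 1.0
    wood_density_kg_m3: 330
    source: "synthetic stand-in (ground-measurement-style DTB,H volume model)"
  kizha_han:
    form: log_log
    predictors: [DBH]
    predictor_units: cm
    response: agb_kg
    coefficients:
      beta0: -2.40
      beta1: 2.38
    correction_factor: 1.024
    wood_density_kg_m3: 330
    source: "synthetic stand-in (harvest-calibrated DBH-only log-log model with back-transform correction)"
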