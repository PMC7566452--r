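# Generalised (non species-specific) above-ground biomass allometries.
# Coefficients transcribed from the original publications:
#   jenkins   — Jenkins et al. (2003), national-scale US equations,
#               softwood cedar/larch species group:
#               AGB_kg = exp(beta0 + beta1 * ln(DBH_cm))
#   chojnacky — Chojnacky et al. (2014) update of the same data,
#               Cupressaceae 0.30-0.39 specific-gravity group, same form.
# Wood density (basic density of coast redwood, kg m^-3) is carried for the
# volume-to-mass conversion shared across the model bank; the log-log models
# themselves predict mass directly and do not use it.
models:
  jenkins:
    form: log_log
    predictors: [DBH]
    predictor_units: cm
    response: agb_kg
    coefficients:
      beta0: -2.0336
      beta1: 2.2592
    correction_factor: 1.0
    wood_density_kg_m3: 330
    source: "Jenkins et al. 2003, cedar/larch group (published coefficients)"
  chojnacky:
    form: log_log
    predictors: [DBH]
    predictor_units: cm
    response: agb_kg
    coefficients:
      beta0: -2.7765
      beta1: 2.4195
    correction_factor: 1.0
    wood_density_kg_m3: 330
    source: "Chojnacky et al. 2014, Cupressaceae 0.30-0.39 sg group (published coefficients)"
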