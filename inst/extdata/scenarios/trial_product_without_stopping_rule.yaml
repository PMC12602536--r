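name: Trial product estimand without a stopping rule
overrides:
  arms.semaglutide.estimand: trial_product
  arms.liraglutide.estimand: trial_product
  model.stopping_rule_enabled: no
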