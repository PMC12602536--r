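name: Trial product estimand with a stopping rule
overrides:
  arms.semaglutide.estimand: trial_product
  arms.liraglutide.estimand: trial_product
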