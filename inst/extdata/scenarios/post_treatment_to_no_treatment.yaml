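name: Post-treatment discontinuation to no treatment
overrides:
  model.post_treatment_pathway: natural
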