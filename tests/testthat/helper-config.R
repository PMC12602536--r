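# Shared fixtures for the suite: the packaged base case and a reduced-horizon
# variant used where many full model runs would be wasteful.

base_cfg <- function() default_config()

short_cfg <- function(horizon = 10) {
  cfg <- default_config()
  config_set(cfg, "model.horizon_years", horizon)
}
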