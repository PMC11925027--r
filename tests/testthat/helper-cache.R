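# The full 20-replicate run of the packaged default configuration takes a
# couple of minutes; several acceptance checks read the same run, so it is
# computed once per test session.
.run_cache <- new.env(parent = emptyenv())

default_ensemble_run <- function() {
  if (is.null(.run_cache$ens)) {
    cfg <- paper_default_config()
    .run_cache$cfg <- cfg
    .run_cache$ens <- run_ensemble(cfg)
  }
  list(cfg = .run_cache$cfg, ens = .run_cache$ens)
}
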