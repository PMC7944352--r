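# Shared heavy fixtures, built once per test session.  The package-level
# caches already memoise the deterministic tables; this env additionally
# memoises experiment runs reused by several tests.

.fx <- new.env(parent = emptyenv())

fx <- function(key, builder) {
  if (!exists(key, .fx, inherits = FALSE)) assign(key, builder(), envir = .fx)
  get(key, .fx)
}

fx_initcond_table <- function() fx("ic_tab", function() initcond_ctm_table())

fx_nk_tables <- function() fx("nk_tabs", function() nk_ctm_tables())

fx_initcond_runs <- function() fx("ic_runs", function() {
  tab <- fx_initcond_table()
  lapply(1:5, function(s) initcond_experiment(tab, seed = s))
})

# Small toy conditional table with CTM(r|r) = 0-like structure is easiest
# to build from an explicit relation; used by classifier unit tests.
toy_cond_table <- function(pairs) build_conditional_ctm(pairs)
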