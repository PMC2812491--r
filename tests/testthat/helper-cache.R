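# Expensive shared fixtures, computed once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

toy_bundle <- function() cached("bundle", build_toy_network())

# the desk-scale recovery run reused by the acceptance checks
toy_recovery <- function() {
  cached("recovery", recovery_experiment(toy_bundle(), seed = 1L))
}
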