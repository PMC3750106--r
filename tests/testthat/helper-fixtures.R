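# Shared fixtures, built once per test session. The EMP/PPP system is the
# expensive one (sparse LU of a ~5600-variable stack), so it is cached.

.fia_cache <- new.env(parent = emptyenv())

toy_net <- function() {
  if (is.null(.fia_cache$toy)) .fia_cache$toy <- toy_fixture()
  .fia_cache$toy
}

toy_sys <- function() {
  if (is.null(.fia_cache$toy_sys)) {
    .fia_cache$toy_sys <- build_fluxomer_system(toy_net()$network)
  }
  .fia_cache$toy_sys
}

toy_sys_full <- function() {
  if (is.null(.fia_cache$toy_sys_full)) {
    .fia_cache$toy_sys_full <-
      build_fluxomer_system(toy_net()$network, reduce = FALSE)
  }
  .fia_cache$toy_sys_full
}

empp <- function() {
  if (is.null(.fia_cache$empp)) .fia_cache$empp <- empp_fixture()
  .fia_cache$empp
}

empp_sys <- function() {
  if (is.null(.fia_cache$empp_sys)) {
    .fia_cache$empp_sys <- build_fluxomer_system(empp()$network)
  }
  .fia_cache$empp_sys
}

empp_fit_cached <- function() {
  if (is.null(.fia_cache$empp_fit)) {
    prob <- flux_problem(empp()$network, empp()$measurements,
                         system = empp_sys())
    .fia_cache$empp_fit <- list(problem = prob, fit = fia_fit(prob))
  }
  .fia_cache$empp_fit
}

# enrichment of atom a from a fraction vector
enrichment_of <- function(fractions, a) {
  k <- round(log2(length(fractions)))
  w <- 0:(2^k - 1L)
  sum(fractions[bitwAnd(bitwShiftR(w, a - 1L), 1L) == 1L])
}
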