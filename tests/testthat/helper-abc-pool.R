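# Shared reference table for the rejection-ABC tests: 20,000 prior draws,
# each simulated once with the desk-scale composite designs (fast MA engine,
# fast recovery engine with one replicate per starting fitness). Built
# lazily on first use and reused by every test that needs it.
.abc_pool_cache <- new.env(parent = emptyenv())

get_abc_pool <- function() {
  if (is.null(.abc_pool_cache$pool)) {
    .abc_pool_cache$pool <- simulate_pool(20000L, seed = 424242L)
  }
  .abc_pool_cache$pool
}
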