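# Shared fixtures: small synthetic signals built in code at test time.

# IBI series object from explicit intervals (ms), bypassing detection
ibi_from_intervals <- function(ibis_ms, t0 = 0) {
  ibi_series(t0 + c(0, cumsum(ibis_ms) / 1000))
}

# a clean modulated recording and its BVP rendering, memoised per session
clean_bvp_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generate_ibi_series(1000, list(list(freq_hz = 0.1, amp_ms = 50)),
                               n_beats = 300L, seed = 11L)
      cache <<- list(truth = g, bvp = synthesize_bvp(g, 256))
    }
    cache
  }
})
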