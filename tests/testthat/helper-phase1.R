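# Shared Phase-I fixture: one synthetic uncensored cohort (n = 5000, the
# default generator settings) with both residual pools fitted on it. Built
# lazily once per session; several test files and the acceptance checks use
# the same Phase-I data, as a real monitoring deployment would.
phase1_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(cohort_config(n = 5000,
                                          censor_horizon_days = Inf,
                                          seed = 101L))
      svr <- fit_svr(co$parsonnet, log(co$time_days))
      aft <- fit_aft(co)
      cache <<- list(cohort = co,
                     svr = svr,
                     aft = aft,
                     pool_svm = sr_svm(co, svr),
                     pool_aft = sr_aft(co, aft))
    }
    cache
  }
})
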