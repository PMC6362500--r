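# Shared fixtures, cached so expensive simulations run once per test session.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# short multiscale scheme for fast cohort-level tests: 60-minute records,
# 1 + 2 + 3 + 12 = 18 segments
short_scheme <- function() scale_scheme(c(60, 30, 20, 5), total_duration = 60)

# small severity-labelled cohort of pyramids on the short scheme
small_pyramid_cohort <- function(n_per_class = 6, seed = 11) {
  cached(sprintf("pyr_%d_%d", n_per_class, seed), {
    cfg <- synthetic_config(duration = 60)
    cohort <- simulate_cohort(n_per_class, cfg, seed = seed)
    scheme <- short_scheme()
    pyramids <- lapply(cohort, function(s) {
      fx <- segment_features(segment_rr(correct_rr(s$rr), scheme),
                             subject_id = s$record$subject_id)
      build_pyramid(fx, scheme)
    })
    list(pyramids = unname(pyramids),
         labels = vapply(cohort, `[[`, character(1), "severity"),
         cohort = cohort)
  })
}

# hand-built pyramid object for pooling tests
fake_pyramid <- function(pools, subject_id = "x") {
  structure(list(subject_id = subject_id, pools = pools,
                 n_expected = length(pools[[1]]),
                 n_realized = length(pools[[1]]), scheme = NULL),
            class = "hrv_pyramid")
}
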