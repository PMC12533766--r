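# shared fixtures: small parameter vectors and cohorts built in code

# constrained 17-vector with flat drifts by mode block
flat_params <- function(v_correct = 2, v_err = 0.5, boost2 = 0.4, boost3 = 0.6,
                        A = 0.8, b = 1.3, t0 = 0.3) {
  p <- c(rep(c(v_correct, v_err, v_err, v_err), 3), boost2, boost3, A, b, t0)
  names(p) <- lba_param_names()
  p
}

# small complete cohort for fast fits
small_cohort <- function(n_per_group = 2, trials_per_mode = 4, seed = 42,
                         pop = true_population()) {
  simulate_dataset(design_spec(n_per_group = n_per_group,
                               trials_per_mode = trials_per_mode,
                               seed = seed),
                   pop, seed = seed + 1)
}

# numeric integral of f on [lo, hi] by trapezoid on a fine grid
trapz_int <- function(f, lo, hi, n = 4000) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
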