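# Shared helpers: small generated datasets used across test files.

design_formulations <- function() {
  fx <- builtin_fixtures()
  fx$formulations[fx$formulations$design_point, ]
}

# exact linear-blend response on the design compositions
exact_linear_response <- function(formulations, beta = c(2, 3, 4)) {
  as.numeric(as.matrix(formulations[, c("pegda", "peg400", "water")]) %*%
               beta)
}

# noiseless power-law profile in hour units
power_profile <- function(k_hour, n, times = c(0.5, 1, 2, 4, 6, 8),
                          id = NULL) {
  dissolution_profile(times, pmin(k_hour * times^n, 100), id = id)
}

# brute-force leave-one-out PRESS: refit with each row dropped
press_brute_force <- function(formulations, response, degree) {
  keep <- !is.na(response)
  formulations <- formulations[keep, , drop = FALSE]
  y <- response[keep]
  n <- length(y)
  sq <- vapply(seq_len(n), function(i) {
    fit_i <- fit_mixture_model(formulations[-i, , drop = FALSE], y[-i],
                               degree)
    xi <- scheffe_terms(c(pegda = formulations$pegda[i],
                          peg400 = formulations$peg400[i],
                          water = formulations$water[i]), degree)
    (y[i] - sum(xi * fit_i$coefficients))^2
  }, numeric(1))
  sum(sq)
}

random_profile_pair <- function(seed) {
  set.seed(seed)
  times <- c(1, 2, 4, 6, 8)
  r <- sort(runif(5, 10, 95))
  t <- pmin(pmax(r + rnorm(5, 0, 6), 0), 100)
  list(times = times, r = r, t = t)
}
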