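#' Pair two dissolution profiles for comparison
#'
#' Model-independent profile comparison requires the reference
#' (experimental) and test (for example surrogate-predicted) curves to be
#' sampled at exactly the same times.
#'
#' @param times Shared sampling times, hours.
#' @param reference Reference (experimental) cumulative percent released.
#' @param test Test (predicted) cumulative percent released.
#' @return An object of class `profile_comparison`.
#' @export
profile_comparison <- function(times, reference, test) {
  stopifnot(length(times) >= 1, length(reference) == length(times),
            length(test) == length(times))
  structure(list(times = as.numeric(times),
                 reference = as.numeric(reference),
                 test = as.numeric(test), n = length(times)),
            class = "profile_comparison")
}

#' Difference factor f1
#'
#' `f1 = 100 * sum(|R_t - T_t|) / sum(R_t)`: the cumulative absolute
#' difference between the curves as a percentage of the reference curve's
#' total. Asymmetric in its arguments (the reference fixes the
#' denominator); 0 for identical profiles, with values up to 15
#' conventionally read as similar.
#'
#' @param cmp A [profile_comparison()].
#' @return The difference factor (dimensionless).
#' @examples
#' fx <- builtin_fixtures()$optimal_comparison
#' f1_difference(profile_comparison(fx$time_h, fx$experimental,
#'                                  fx$predicted_nn1))
#' @export
f1_difference <- function(cmp) {
  if (sum(cmp$reference) <= 0) {
    stop("reference profile sums to zero; f1 is undefined", call. = FALSE)
  }
  100 * sum(abs(cmp$reference - cmp$test)) / sum(cmp$reference)
}

#' Similarity factor f2
#'
#' `f2 = 50 * log10(100 / sqrt(1 + mean((R_t - T_t)^2)))`: a logarithmic
#' transform of the mean squared difference. 100 for identical profiles,
#' 50 at a uniform offset of sqrt(99) (about 9.95 percentage points);
#' values of 50 and above are conventionally read as similar.
#'
#' By default every supplied time point enters the statistic. The
#' regulatory practice of dropping points after the first exceeding 85
#' percent release is available with `truncate_85 = TRUE`.
#'
#' @param cmp A [profile_comparison()].
#' @param truncate_85 Keep at most one point beyond 85 percent reference
#'   release.
#' @return The similarity factor (dimensionless, at most 100).
#' @examples
#' fx <- builtin_fixtures()$optimal_comparison
#' f2_similarity(profile_comparison(fx$time_h, fx$experimental,
#'                                  fx$predicted_nn1))
#' @export
f2_similarity <- function(cmp, truncate_85 = FALSE) {
  r <- cmp$reference
  t <- cmp$test
  if (truncate_85) {
    over <- which(r > 85)
    if (length(over) > 1) {
      keep <- seq_len(over[1])
      r <- r[keep]; t <- t[keep]
    }
  }
  50 * log10(100 / sqrt(1 + mean((r - t)^2)))
}

#' Squared observed-versus-predicted correlation
#'
#' @param cmp A [profile_comparison()] with at least two points and
#'   non-constant series.
#' @return Squared Pearson correlation of the two series.
#' @export
r2_obs_pred <- function(cmp) {
  if (cmp$n < 2) stop("need at least 2 points", call. = FALSE)
  if (stats::sd(cmp$reference) == 0 || stats::sd(cmp$test) == 0) {
    stop("correlation undefined for a constant series", call. = FALSE)
  }
  stats::cor(cmp$reference, cmp$test)^2
}

#' Similarity verdict from f1 and f2
#'
#' The conventional regulatory bands: profiles are similar when f1 is at
#' most 15 and f2 is at least 50.
#'
#' @param f1,f2 Difference and similarity factors.
#' @return `"similar"` or `"not_similar"`.
#' @export
similarity_verdict <- function(f1, f2) {
  if (f1 <= 15 && f2 >= 50) "similar" else "not_similar"
}

#' Full model-independent comparison of two profiles
#'
#' @inheritParams profile_comparison
#' @return A one-row tibble with `f1`, `f2`, `r2`, `verdict`.
#' @examples
#' fx <- builtin_fixtures()$optimal_comparison
#' compare_profiles(fx$time_h, fx$experimental, fx$predicted_nn1)
#' @export
compare_profiles <- function(times, reference, test) {
  cmp <- profile_comparison(times, reference, test)
  f1 <- f1_difference(cmp)
  f2 <- f2_similarity(cmp)
  tibble::tibble(f1 = f1, f2 = f2, r2 = r2_obs_pred(cmp),
                 verdict = similarity_verdict(f1, f2))
}
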