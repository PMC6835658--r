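#' Release goal for desirability optimization
#'
#' Each goal targets the cumulative release at one time point with a
#' one-sided desirability ramp: for `at_most`, d = 1 up to `limit` and
#' falls linearly to 0 at `limit + ramp_width`; `at_least` is mirrored
#' (d = 1 from `limit` upward, 0 at `limit - ramp_width`). Importance
#' weights (integer "pluses") enter the overall desirability as exponents.
#'
#' @param time Time point, hours.
#' @param direction `"at_most"` or `"at_least"`.
#' @param limit Release limit, percent of dose, in (0, 100).
#' @param importance Integer weight, at least 1.
#' @param ramp_width Width of the linear transition, percentage points.
#' @return An object of class `goal_spec`.
#' @export
goal_spec <- function(time, direction = c("at_most", "at_least"), limit,
                      importance = 1L, ramp_width = 20) {
  direction <- match.arg(direction)
  stopifnot(limit > 0, limit < 100, importance >= 1, ramp_width > 0)
  structure(list(time = time, direction = direction, limit = limit,
                 importance = as.integer(importance),
                 ramp_width = ramp_width),
            class = "goal_spec")
}

#' The extended-release target profile used for printlet optimization
#'
#' Release of at most 30 / 60 / 70 percent at 2 / 4 / 6 h and at least 80
#' percent at 8 h. The late goals carry importance 3 ("three pluses")
#' against 2 for the early ones, because reaching near-complete release by
#' 8 h matters more than the exact early shape.
#'
#' @param ramp_width Transition width passed to every [goal_spec()].
#' @return A list of four `goal_spec` objects.
#' @export
default_release_goals <- function(ramp_width = 20) {
  list(
    goal_spec(2, "at_most", 30, importance = 2, ramp_width = ramp_width),
    goal_spec(4, "at_most", 60, importance = 2, ramp_width = ramp_width),
    goal_spec(6, "at_most", 70, importance = 3, ramp_width = ramp_width),
    goal_spec(8, "at_least", 80, importance = 3, ramp_width = ramp_width)
  )
}

#' Per-goal desirability
#'
#' @param value Observed/predicted release, percent (vectorized).
#' @param goal A [goal_spec()].
#' @param hard Use a hard 0/1 threshold instead of the linear ramp.
#' @return Desirability in \[0, 1\].
#' @examples
#' goal_desirability(35, goal_spec(2, "at_most", 30, 2, ramp_width = 20))
#' @export
goal_desirability <- function(value, goal, hard = FALSE) {
  if (hard) {
    ok <- if (goal$direction == "at_most") value <= goal$limit else
      value >= goal$limit
    return(as.numeric(ok))
  }
  if (goal$direction == "at_most") {
    d <- 1 - (value - goal$limit) / goal$ramp_width
  } else {
    d <- 1 - (goal$limit - value) / goal$ramp_width
  }
  pmin(pmax(d, 0), 1)
}

#' Overall desirability: weighted geometric mean
#'
#' `D = (prod d_i^r_i)^(1 / sum r_i)`. D is 0 whenever any single goal is
#' fully violated, lies between min(d) and max(d), and is invariant to a
#' uniform rescaling of the importances.
#'
#' @param d Per-goal desirabilities in \[0, 1\].
#' @param importance Integer weights, same length as `d`.
#' @return Overall desirability D in \[0, 1\].
#' @export
overall_desirability <- function(d, importance = rep(1, length(d))) {
  stopifnot(length(d) == length(importance), all(d >= 0), all(d <= 1))
  if (any(d == 0)) return(0)
  exp(sum(importance * log(d)) / sum(importance))
}

# Evaluate one composition: predicted releases at the goal times,
# per-goal d, overall D.
evaluate_candidate <- function(comp, surrogate, goals, bounds, hard) {
  f <- list(pegda = comp[1], peg400 = comp[2], water = comp[3])
  n_in <- surrogate$config$layer_sizes[1]
  exposure <- if (n_in == 4) exposure_time_rule(f$water) else NULL
  pred <- predict_release(surrogate, f, exposure_time = exposure)
  goal_times <- vapply(goals, function(g) g$time, numeric(1))
  idx <- match(goal_times, pred$time_h)
  if (any(is.na(idx))) {
    stop("surrogate time grid lacks goal time(s): ",
         paste(goal_times[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  vals <- pred$released_pct[idx]
  d <- vapply(seq_along(goals), function(i)
    goal_desirability(vals[i], goals[[i]], hard = hard), numeric(1))
  r <- vapply(goals, function(g) g$importance, numeric(1))
  list(D = overall_desirability(d, r), d = d, values = vals, pred = pred)
}

#' Optimize a formulation against release goals using a surrogate
#'
#' Maximizes the overall desirability of the surrogate-predicted release
#' profile over the bounded mixture simplex: a seed-controlled multi-start
#' (coarse candidate sample plus the simplex vertices and centroid)
#' followed by Nelder-Mead refinement of the best starts in the
#' (PEGDA, PEG 400) plane, with water taking the mixture slack and
#' out-of-bounds moves rejected. Deterministic given the seed.
#'
#' For 4-input surrogates the candidate's exposure time is derived from
#' its water content via [exposure_time_rule()].
#'
#' @param surrogate A trained `mlp` release model (3 or 4 inputs).
#' @param bounds A [design_bounds()] object.
#' @param goals List of [goal_spec()]; defaults to
#'   [default_release_goals()].
#' @param n_starts Number of random starting compositions.
#' @param seed Integer seed.
#' @param hard Use hard 0/1 desirability instead of the linear ramps.
#' @return A list of class `desirability_result`: `composition`
#'   (formulation tibble row), `overall_D`, `per_goal_d`,
#'   `predicted_profile`, `feasible` (`FALSE` when every start gave
#'   D = 0; the best-found profile is still reported).
#' @export
optimize_formulation <- function(surrogate, bounds = design_bounds(),
                                 goals = default_release_goals(),
                                 n_starts = 20, seed = 1L, hard = FALSE) {
  starts <- rbind(sample_bounded_simplex(n_starts, bounds, seed),
                  simplex_vertices(bounds),
                  matrix(colMeans(simplex_vertices(bounds)), 1))
  lo <- bounds$lower; hi <- bounds$upper; total <- bounds$mixture_total
  objective <- function(xy) {
    comp <- c(xy[1], xy[2], total - xy[1] - xy[2])
    if (any(comp < lo - 1e-9) || any(comp > hi + 1e-9)) return(1)
    -evaluate_candidate(comp, surrogate, goals, bounds, hard)$D
  }
  scores <- apply(starts, 1, function(s) objective(s[1:2]))
  top <- starts[order(scores)[seq_len(min(5, nrow(starts)))], ,
                drop = FALSE]
  best <- list(val = Inf, xy = top[1, 1:2])
  for (i in seq_len(nrow(top))) {
    opt <- stats::optim(top[i, 1:2], objective, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
    if (opt$value < best$val) best <- list(val = opt$value, xy = opt$par)
  }
  comp <- c(best$xy[1], best$xy[2], total - sum(best$xy))
  comp <- unname(pmin(pmax(comp, lo), hi))
  res <- evaluate_candidate(comp, surrogate, goals, bounds, hard)
  composition <- tibble::tibble(
    id = "optimal", pegda = comp[1], peg400 = comp[2], water = comp[3],
    riboflavin = bounds$riboflavin, ibuprofen = bounds$ibuprofen)
  structure(list(composition = composition, overall_D = res$D,
                 per_goal_d = res$d, predicted_profile = res$pred,
                 goal_values = res$values, feasible = res$D > 0),
            class = "desirability_result")
}

#' @export
print.desirability_result <- function(x, ...) {
  cat(sprintf("Optimal composition (D = %.4f%s):\n", x$overall_D,
              if (x$feasible) "" else "; no feasible point found"))
  cat(sprintf("  PEGDA %.2f%%, PEG 400 %.2f%%, water %.2f%%\n",
              x$composition$pegda, x$composition$peg400,
              x$composition$water))
  cat("Predicted release:\n")
  print(x$predicted_profile)
  invisible(x)
}
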