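#' Scheffe canonical polynomial terms for a three-component mixture
#'
#' Because mixture components sum to a constant, mixture polynomials are
#' fitted in the Scheffe canonical form, which has no intercept: the linear
#' blending terms absorb it.
#'
#' @param x Numeric vector of the 3 component values (actual percent w/w).
#' @param degree One of `"linear"`, `"quadratic"`, `"special_cubic"`,
#'   `"full_cubic"`.
#' @return Named numeric vector of model terms: linear `(x1, x2, x3)`;
#'   quadratic adds the pairwise products; special cubic adds `x1 x2 x3`;
#'   full cubic further adds the three cross-difference terms
#'   `x_i x_j (x_i - x_j)` (10 terms in all).
#' @examples
#' scheffe_terms(c(2, 3, 5), "quadratic")
#' @export
scheffe_terms <- function(x, degree = c("linear", "quadratic",
                                        "special_cubic", "full_cubic")) {
  degree <- match.arg(degree)
  stopifnot(length(x) == 3, is.numeric(x))
  nm <- if (!is.null(names(x)) && all(nzchar(names(x)))) names(x) else
    c("x1", "x2", "x3")
  out <- stats::setNames(as.numeric(x), nm)
  if (degree == "linear") return(out)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  quad <- vapply(pairs, function(p) x[p[1]] * x[p[2]], numeric(1))
  names(quad) <- vapply(pairs, function(p) paste(nm[p], collapse = ":"),
                        character(1))
  out <- c(out, quad)
  if (degree == "quadratic") return(out)
  out <- c(out, stats::setNames(prod(x), paste(nm, collapse = ":")))
  if (degree == "special_cubic") return(out)
  cross <- vapply(pairs, function(p) x[p[1]] * x[p[2]] * (x[p[1]] - x[p[2]]),
                  numeric(1))
  names(cross) <- vapply(pairs, function(p)
    sprintf("%s:%s:(%s-%s)", nm[p[1]], nm[p[2]], nm[p[1]], nm[p[2]]),
    character(1))
  c(out, cross)
}

scheffe_model_matrix <- function(formulations, degree) {
  X <- t(vapply(seq_len(nrow(formulations)), function(i) {
    x <- c(pegda = formulations$pegda[i], peg400 = formulations$peg400[i],
           water = formulations$water[i])
    scheffe_terms(x, degree)
  }, scheffe_terms(c(pegda = 1, peg400 = 1, water = 1), degree)))
  X
}

#' Fit a Scheffe mixture polynomial to a tablet response
#'
#' No-intercept least squares of the response on the canonical mixture
#' terms in actual percent-w/w units. Rows with a missing response are
#' dropped before fitting (for example a hardness that could not be
#' measured).
#'
#' Fit statistics follow the mixture-model conventions of design-of-
#' experiments software: R-squared is computed against the mean-corrected
#' total sum of squares; because the fixed-sum constraint removes one
#' effective parameter, a model with `t` canonical terms has model df
#' `t - 1` and residual df `n - t`, so
#' `adj_r2 = 1 - (1 - r2) * (n - 1) / (n - t)`. PRESS is the leave-one-out
#' predicted residual sum of squares computed from the hat diagonal, and
#' `pred_r2 = 1 - PRESS / SS_total`.
#'
#' @param formulations Formulation tibble (only `pegda`, `peg400`, `water`
#'   enter the model).
#' @param response Numeric response, one value per formulation; `NA` drops
#'   the row.
#' @param degree Scheffe degree, as in [scheffe_terms()].
#' @param response_name Label used in printing.
#' @return An object of class `mixture_fit`: `degree`, `terms`,
#'   `coefficients`, `fitted`, `residuals`, `n_obs`, `r2`, `adj_r2`,
#'   `press`, `pred_r2`, `residual_df`, `leverages`, plus the design matrix
#'   and kept responses for downstream leave-one-out work.
#' @examples
#' fx <- builtin_fixtures()
#' des <- fx$formulations[fx$formulations$design_point, ]
#' fit_mixture_model(des, fx$tablet_properties$weight_mg, "linear", "weight")
#' @export
fit_mixture_model <- function(formulations, response,
                              degree = c("linear", "quadratic",
                                         "special_cubic", "full_cubic"),
                              response_name = "response") {
  degree <- match.arg(degree)
  stopifnot(nrow(formulations) == length(response))
  keep <- !is.na(response)
  formulations <- formulations[keep, , drop = FALSE]
  y <- response[keep]
  X <- scheffe_model_matrix(formulations, degree)
  n <- nrow(X)
  t_terms <- ncol(X)
  if (n <= t_terms) {
    stop("cannot fit ", degree, " model: ", n, " observations for ",
         t_terms, " terms leaves no residual df", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < t_terms) {
    stop("rank-deficient design for degree '", degree, "'", call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  fitted <- drop(X %*% coefs)
  res <- y - fitted
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - t_terms)
  h <- rowSums(qr.Q(qrX)[, seq_len(t_terms), drop = FALSE]^2)
  if (any(h >= 1 - 1e-12)) {
    press <- NA_real_
    pred_r2 <- NA_real_
  } else {
    press <- sum((res / (1 - h))^2)
    pred_r2 <- 1 - press / ss_tot
  }
  structure(list(
    degree = degree, terms = colnames(X), coefficients = coefs,
    fitted = fitted, residuals = res, n_obs = n, r2 = r2, adj_r2 = adj_r2,
    press = press, pred_r2 = pred_r2, residual_df = n - t_terms,
    leverages = h, X = X, y = y, ss_total = ss_tot,
    response_name = response_name
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Scheffe %s mixture model for %s (n = %d)\n", x$degree,
              x$response_name, x$n_obs))
  print(round(x$coefficients, 5))
  cat(sprintf("R2 %.4f | adj R2 %.4f | pred R2 %s | PRESS %s\n", x$r2,
              x$adj_r2,
              ifelse(is.na(x$pred_r2), "n.d.", sprintf("%.4f", x$pred_r2)),
              ifelse(is.na(x$press), "n.d.", sprintf("%.2f", x$press))))
  invisible(x)
}

#' Leave-one-out PRESS and predicted R-squared
#'
#' Computed via the hat-diagonal identity `e_i / (1 - h_ii)` for the
#' out-of-sample residual of observation i, which equals refitting with
#' that observation removed.
#'
#' @param fit A [fit_mixture_model()] object.
#' @return A list with `press` and `pred_r2`.
#' @export
press_loo <- function(fit) {
  h <- fit$leverages
  if (any(h >= 1 - 1e-12)) {
    stop("a leverage equals 1: that observation cannot be predicted ",
         "out-of-sample", call. = FALSE)
  }
  press <- sum((fit$residuals / (1 - h))^2)
  list(press = press, pred_r2 = 1 - press / fit$ss_total)
}

#' Fit all Scheffe degrees and tabulate their summary statistics
#'
#' Degrees whose term count leaves no residual degrees of freedom are
#' reported as unavailable (`NA` statistics) rather than fitted.
#'
#' @inheritParams fit_mixture_model
#' @return A list with `fits` (named list of `mixture_fit` or `NULL`) and
#'   `summary` (tibble of degree, adj_r2, pred_r2, press, available).
#' @export
fit_all_degrees <- function(formulations, response,
                            response_name = "response") {
  degrees <- c("linear", "quadratic", "special_cubic", "full_cubic")
  fits <- stats::setNames(vector("list", length(degrees)), degrees)
  rows <- lapply(degrees, function(d) {
    f <- tryCatch(fit_mixture_model(formulations, response, d,
                                    response_name),
                  error = function(e) NULL)
    fits[[d]] <<- f
    if (is.null(f)) {
      tibble::tibble(degree = d, r2 = NA_real_, adj_r2 = NA_real_,
                     pred_r2 = NA_real_, press = NA_real_,
                     available = FALSE)
    } else {
      tibble::tibble(degree = d, r2 = f$r2, adj_r2 = f$adj_r2,
                     pred_r2 = f$pred_r2, press = f$press, available = TRUE)
    }
  })
  list(fits = fits, summary = do.call(rbind, rows))
}

#' Select the best-fitting mixture model
#'
#' Joint maximization of the adjusted and the predicted R-squared: models
#' whose leave-one-out predicted R-squared is negative (out-of-sample
#' prediction worse than the response mean — the signature of an overfit
#' higher-degree mixture polynomial on a small design) are only chosen
#' when no model predicts better than the mean; within the preferred set
#' the adjusted R-squared is maximized, with the predicted R-squared as
#' tie-breaker. Unavailable degrees are recorded but never chosen.
#'
#' @param fits A named list of [fit_mixture_model()] objects (entries may
#'   be `NULL` for degrees that could not be fitted).
#' @return A list with `chosen` (the winning `mixture_fit`), `degree`, and
#'   `rationale` (tibble of candidate statistics with an `unavailable`
#'   marker).
#' @export
select_model <- function(fits) {
  avail <- Filter(Negate(is.null), fits)
  if (length(avail) == 0) stop("no fitted model available", call. = FALSE)
  adj <- vapply(avail, function(f) f$adj_r2, numeric(1))
  pred <- vapply(avail, function(f) {
    if (is.na(f$pred_r2)) -Inf else f$pred_r2
  }, numeric(1))
  generalizes <- pred >= 0
  best <- order(-generalizes, -adj, -pred)[1]
  rationale <- tibble::tibble(
    degree = names(fits),
    adj_r2 = vapply(fits, function(f) if (is.null(f)) NA_real_ else
      f$adj_r2, numeric(1)),
    pred_r2 = vapply(fits, function(f) if (is.null(f)) NA_real_ else
      f$pred_r2, numeric(1)),
    available = !vapply(fits, is.null, logical(1))
  )
  list(chosen = avail[[best]], degree = names(avail)[best],
       rationale = rationale)
}

## ---- D-optimal design ------------------------------------------------

# Extreme vertices of {lower <= x <= upper, sum(x) = total} for 3
# components: fix each pair of components at bound combinations and keep
# the slack component when it lands inside its own bounds.
simplex_vertices <- function(bounds) {
  lo <- bounds$lower; hi <- bounds$upper; total <- bounds$mixture_total
  verts <- list()
  for (free in 1:3) {
    others <- setdiff(1:3, free)
    for (b1 in c(lo[others[1]], hi[others[1]])) {
      for (b2 in c(lo[others[2]], hi[others[2]])) {
        x <- numeric(3)
        x[others] <- c(b1, b2)
        x[free] <- total - b1 - b2
        if (x[free] >= lo[free] - 1e-9 && x[free] <= hi[free] + 1e-9) {
          verts[[length(verts) + 1]] <- pmin(pmax(x, lo), hi)
        }
      }
    }
  }
  if (length(verts) == 0) return(matrix(numeric(0), 0, 3))
  V <- unique(round(do.call(rbind, verts), 9))
  colnames(V) <- names(lo)
  V
}

candidate_set <- function(bounds, n_candidates, seed) {
  V <- simplex_vertices(bounds)
  mids <- NULL
  if (nrow(V) >= 2) {
    idx <- utils::combn(nrow(V), 2)
    mids <- t(apply(idx, 2, function(p) (V[p[1], ] + V[p[2], ]) / 2))
  }
  centroid <- matrix(colMeans(V), 1, 3)
  cand <- rbind(V, mids, centroid)
  n_fill <- max(n_candidates - nrow(cand), 0)
  if (n_fill > 0) {
    cand <- rbind(cand, sample_bounded_simplex(n_fill, bounds, seed))
  }
  colnames(cand) <- component_names()
  unique(cand)
}

design_logdet <- function(X) {
  d <- determinant(crossprod(X), logarithm = TRUE)
  if (d$sign <= 0) -Inf else as.numeric(d$modulus)
}

#' Generate a D-optimal mixture design by Fedorov exchange
#'
#' Builds a candidate set (extreme vertices of the bounded simplex, edge
#' midpoints, the centroid, and seed-controlled random fill), then
#' exchanges design points against candidates, accepting any swap that
#' increases det(X'X) of the Scheffe model matrix, until no swap improves
#' or `max_iter` passes complete. Deterministic given the seed.
#'
#' @param bounds A [design_bounds()] object.
#' @param n_runs Number of design points; must be at least the number of
#'   model terms.
#' @param degree Scheffe degree of the model the design targets.
#' @param n_candidates Size of the candidate pool.
#' @param seed Integer seed for the random fill and initial design.
#' @param max_iter Maximum exchange passes.
#' @return A list with `design` (formulation tibble, ids `D1..Dn`),
#'   `log_det` (final log det(X'X)), `log_det_trace` (value after each
#'   accepted swap, non-decreasing), and `candidates`.
#' @export
doptimal_design <- function(bounds = design_bounds(), n_runs = 11,
                            degree = "linear", n_candidates = 200,
                            seed = 1L, max_iter = 50) {
  n_terms <- length(scheffe_terms(c(1, 1, 1), degree))
  if (n_runs < n_terms) {
    stop("n_runs (", n_runs, ") is below the number of model terms (",
         n_terms, ")", call. = FALSE)
  }
  cand <- candidate_set(bounds, n_candidates, seed)
  cand_X <- t(apply(cand, 1, function(x)
    scheffe_terms(stats::setNames(x, component_names()), degree)))
  set.seed(seed)
  # random full-rank start
  cur <- sample(nrow(cand), n_runs)
  for (attempt in 1:100) {
    if (qr(cand_X[cur, , drop = FALSE])$rank == n_terms) break
    cur <- sample(nrow(cand), n_runs)
  }
  best_ld <- design_logdet(cand_X[cur, , drop = FALSE])
  trace <- best_ld
  for (pass in seq_len(max_iter)) {
    improved <- FALSE
    for (i in seq_len(n_runs)) {
      for (j in seq_len(nrow(cand))) {
        if (j %in% cur) next
        trial <- cur
        trial[i] <- j
        ld <- design_logdet(cand_X[trial, , drop = FALSE])
        if (ld > best_ld + 1e-10) {
          cur <- trial
          best_ld <- ld
          trace <- c(trace, ld)
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  pts <- cand[cur, , drop = FALSE]
  design <- tibble::tibble(
    id = paste0("D", seq_len(n_runs)),
    pegda = pts[, "pegda"], peg400 = pts[, "peg400"],
    water = pts[, "water"],
    riboflavin = bounds$riboflavin, ibuprofen = bounds$ibuprofen
  )
  list(design = design, log_det = best_ld, log_det_trace = trace,
       candidates = cand)
}
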