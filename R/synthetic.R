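#' Ground-truth release model for synthetic studies
#'
#' Synthetic dissolution curves follow a composition-linked power law
#' Q(t) = k * t^n (t in hours) with
#' `k = k_base + k_peg * peg400 + k_pegda * pegda` and
#' `n = n_base + n_water * water`, clamped to (0.05, 1). The power-law
#' backbone mirrors the diffusion-dominated (square-root-of-time to
#' anomalous) release observed from photocrosslinked PEGDA matrices: more
#' PEG 400 loosens the network and speeds release, more PEGDA slows it.
#'
#' Defaults are chosen so that 8-hour release across the design region
#' spans roughly 35-90 percent of dose (the range reported for printed
#' PEGDA/PEG 400/water tablets), with release exponents in the Fickian to
#' mildly anomalous band (about 0.36-0.44) and replicate noise of a couple
#' of percent.
#'
#' @param k_base Baseline release rate, percent per hour^n.
#' @param k_peg Sensitivity of the rate to PEG 400, per percent w/w.
#' @param k_pegda Sensitivity of the rate to PEGDA, per percent w/w
#'   (negative: crosslinker slows release).
#' @param n_base Baseline release exponent (dimensionless).
#' @param n_water Sensitivity of the exponent to water, per percent w/w.
#' @param noise_sd Additive Gaussian replicate noise, percent of dose.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(k_base = 20, k_peg = 0.30, k_pegda = -0.10,
                         n_base = 0.32, n_water = 0.004, noise_sd = 2.0) {
  stopifnot(noise_sd >= 0)
  structure(list(k_base = k_base, k_peg = k_peg, k_pegda = k_pegda,
                 n_base = n_base, n_water = n_water, noise_sd = noise_sd),
            class = "ground_truth")
}

truth_params <- function(truth, f) {
  k <- truth$k_base + truth$k_peg * f$peg400 + truth$k_pegda * f$pegda
  n <- truth$n_base + truth$n_water * f$water
  n <- pmin(pmax(n, 0.05), 1.0)
  list(k = k, n = n)
}

#' Feasibility of bounded-simplex sampling
#'
#' The intersection of the box `lower <= x <= upper` with the plane
#' `sum(x) = mixture_total` is non-empty exactly when
#' `sum(lower) <= mixture_total <= sum(upper)`.
#'
#' @param bounds A [design_bounds()] object.
#' @return `TRUE` or `FALSE`.
#' @export
bounds_feasible <- function(bounds) {
  sum(bounds$lower) <= bounds$mixture_total &&
    bounds$mixture_total <= sum(bounds$upper)
}

# Uniform rejection sampler on {lower <= x <= upper, sum(x) = total};
# returns an n x 3 matrix. Shared by the study generator and the
# D-optimal candidate fill.
sample_bounded_simplex <- function(n, bounds, seed) {
  if (!bounds_feasible(bounds)) {
    stop("infeasible bounds: no composition with components in bounds sums ",
         "to mixture_total = ", bounds$mixture_total, call. = FALSE)
  }
  set.seed(seed)
  total <- bounds$mixture_total
  lo <- bounds$lower
  hi <- bounds$upper
  got <- matrix(NA_real_, 0, 3)
  max_batches <- 10000
  while (nrow(got) < n && max_batches > 0) {
    m <- max(4L * n, 64L)
    pegda <- stats::runif(m, lo[1], hi[1])
    peg400 <- stats::runif(m, lo[2], hi[2])
    water <- total - pegda - peg400
    ok <- water >= lo[3] & water <= hi[3]
    got <- rbind(got, cbind(pegda, peg400, water)[ok, , drop = FALSE])
    max_batches <- max_batches - 1
  }
  if (nrow(got) < n) {
    stop("could not sample the bounded simplex; the feasible region is ",
         "degenerate for these bounds", call. = FALSE)
  }
  colnames(got) <- c("pegda", "peg400", "water")
  got[seq_len(n), , drop = FALSE]
}

#' Sample formulations uniformly on the bounded mixture simplex
#'
#' Rejection sampling: the first two components are drawn uniformly in
#' their boxes, the third is the remaining slack, and draws with the third
#' component outside its bounds are rejected. This is uniform on the
#' feasible polytope (the plane-section of a box under a fixed-sum
#' constraint).
#'
#' @param n Number of formulations.
#' @param bounds A [design_bounds()] object.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A formulation tibble: the three sampled components plus the
#'   fixed riboflavin and ibuprofen levels, ids `S1..Sn`.
#' @export
generate_formulations <- function(n, bounds = design_bounds(), seed = 1L) {
  got <- sample_bounded_simplex(n, bounds, seed)
  as_formulation_table(tibble::tibble(
    id = paste0("S", seq_len(n)),
    pegda = got[, 1], peg400 = got[, 2], water = got[, 3],
    riboflavin = bounds$riboflavin, ibuprofen = bounds$ibuprofen
  ))
}

#' Exposure time required to cure a resin, from its water content
#'
#' Water dilutes the photoreactive monomer, so wetter resins need longer
#' light exposure per layer to solidify. The rule is a monotone
#' non-decreasing step function over water content (percent w/w) matching
#' the majority pattern of the published printing settings; it is used for
#' de-novo (synthetic or optimized) compositions.
#'
#' @param water Water content, percent w/w (vectorized).
#' @return Exposure time in seconds.
#' @examples
#' exposure_time_rule(c(5, 10.1, 30))
#' @export
exposure_time_rule <- function(water) {
  stopifnot(all(water >= 0))
  breaks <- c(-Inf, 7.5, 12.5, 17.5, 22.5, Inf)
  secs <- c(100, 400, 500, 600, 800)
  secs[findInterval(water, breaks, left.open = FALSE)]
}

#' Simulate a dissolution profile for one formulation
#'
#' The noiseless curve is the ground-truth power law; Gaussian noise of
#' `truth$noise_sd` percent is added per point, then the curve is made
#' non-decreasing by a running maximum and capped at 100 (a cumulative
#' release curve cannot decrease and cannot exceed the dose).
#'
#' @param f A one-row formulation (list or data frame row).
#' @param times Sampling times in hours, strictly increasing.
#' @param truth A [ground_truth()] object.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A [dissolution_profile()].
#' @export
simulate_dissolution <- function(f, times = c(0.5, 1, 2, 4, 6, 8),
                                 truth = ground_truth(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- truth_params(truth, f)
  if (p$k <= 0) {
    stop("non-positive release rate k = ", signif(p$k, 4),
         " for this composition; adjust the ground-truth sensitivities",
         call. = FALSE)
  }
  q <- p$k * times^p$n
  if (truth$noise_sd > 0) {
    q <- q + stats::rnorm(length(times), 0, truth$noise_sd)
  }
  q <- pmin(pmax(cummax(q), 0), 100)
  dissolution_profile(times, q, id = if (!is.null(f$id)) f$id)
}

#' Generate a complete synthetic dissolution study
#'
#' Formulations sampled on the bounded simplex, exposure times from
#' [exposure_time_rule()], and one simulated profile per formulation on a
#' common time grid. The default grid is 1/2/4/6/8 h plus an early 0.5 h
#' point that stabilizes kinetic fits.
#'
#' @param n Number of formulations.
#' @param truth A [ground_truth()] object.
#' @param seed Integer seed controlling both sampling and noise.
#' @param bounds A [design_bounds()] object.
#' @param times Shared sampling grid in hours.
#' @return A list of class `synthetic_study` with elements `formulations`,
#'   `print_parameters`, `profiles` (named list of profiles), `truth`,
#'   `times`, `seed`.
#' @export
generate_study <- function(n = 11, truth = ground_truth(), seed = 1L,
                           bounds = design_bounds(),
                           times = c(0.5, 1, 2, 4, 6, 8)) {
  formulations <- generate_formulations(n, bounds, seed = seed)
  print_parameters <- tibble::tibble(
    id = formulations$id,
    exposure_time_s = exposure_time_rule(formulations$water),
    bottom_exposure_s = 800,
    layer_thickness_mm = 0.10,
    bottom_layers = 10L
  )
  set.seed(seed + 1L)
  profiles <- lapply(seq_len(n), function(i) {
    simulate_dissolution(formulations[i, ], times, truth)
  })
  names(profiles) <- formulations$id
  structure(list(formulations = formulations,
                 print_parameters = print_parameters,
                 profiles = profiles, truth = truth, times = times,
                 seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic dissolution study:", nrow(x$formulations),
      "formulations, grid", paste(x$times, collapse = "/"), "h, seed",
      x$seed, "\n")
  invisible(x)
}

#' Write a synthetic study to a directory of plain-text files
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly. Writes `formulations.csv`,
#'   `print_parameters.csv`, `profiles.csv` and `truth.yaml`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_formulation_table(study$formulations,
                          file.path(dir, "formulations.csv"))
  utils::write.csv(study$print_parameters,
                   file.path(dir, "print_parameters.csv"),
                   row.names = FALSE, quote = FALSE)
  write_profile_table(study$profiles, file.path(dir, "profiles.csv"))
  yaml::write_yaml(c(unclass(study$truth), list(seed = study$seed)),
                   file.path(dir, "truth.yaml"))
  invisible(dir)
}
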