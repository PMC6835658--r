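test_that("Scheffe canonical terms follow the no-intercept expansion", {
  expect_equal(unname(scheffe_terms(c(1, 0, 0), "linear")), c(1, 0, 0))
  expect_equal(unname(scheffe_terms(c(2, 3, 5), "quadratic")),
               c(2, 3, 5, 6, 10, 15))
  expect_equal(unname(scheffe_terms(c(2, 3, 5), "special_cubic")),
               c(2, 3, 5, 6, 10, 15, 30))
  fc <- scheffe_terms(c(1, 1, 1), "full_cubic")
  expect_length(fc, 10)
  expect_equal(unname(fc[8:10]), c(0, 0, 0))  # cross-differences vanish
  expect_error(scheffe_terms(c(1, 2, 3), "septic"))
})

test_that("an exact linear blend is recovered to machine precision", {
  des <- design_formulations()
  y <- exact_linear_response(des, c(2, 3, 4))
  fit <- fit_mixture_model(des, y, "linear")
  expect_equal(unname(fit$coefficients), c(2, 3, 4), tolerance = 1e-10)
  expect_equal(fit$r2, 1)
  loo <- press_loo(fit)
  expect_equal(loo$press, 0, tolerance = 1e-12)
  expect_equal(loo$pred_r2, 1)
})

test_that("published linear-blend coefficients refit from the study tables", {
  fx <- builtin_fixtures()
  des <- design_formulations()

  fw <- fit_mixture_model(des, fx$tablet_properties$weight_mg, "linear")
  expect_equal(unname(fw$coefficients),
               c(2.68392, 3.78589, 6.42698), tolerance = 0.01)

  fh <- fit_mixture_model(des, fx$tablet_properties$hardness_n, "linear")
  expect_equal(fh$n_obs, 10)  # the unmeasured hardness row is dropped
  expect_equal(unname(fh$coefficients),
               c(1.52104, -0.53285, -0.28236), tolerance = 0.01)

  fd <- fit_mixture_model(des, fx$tablet_properties$drug_load_mg, "linear")
  expect_equal(unname(fd$coefficients),
               c(0.11399, 0.24544, 0.53252), tolerance = 0.01)

  # raw R2 of the three linear fits, as reported in the study
  expect_equal(c(fw$r2, fh$r2, fd$r2), c(0.586, 0.578, 0.615),
               tolerance = 0.01)
})

test_that("model summary statistics reproduce the published weight row", {
  fx <- builtin_fixtures()
  fit <- fit_mixture_model(design_formulations(),
                           fx$tablet_properties$weight_mg, "linear")
  expect_equal(fit$adj_r2, 0.4828, tolerance = 0.01)
  expect_equal(fit$press, 11760.57, tolerance = 0.01 * 11760.57)
  expect_equal(fit$pred_r2, 0.2042, tolerance = 0.01)
  expect_equal(fit$residual_df, 8)
})

test_that("hat-matrix PRESS equals explicit leave-one-out refits", {
  fx <- builtin_fixtures()
  des <- design_formulations()
  cases <- list(
    list(y = fx$tablet_properties$weight_mg, degree = "linear"),
    list(y = fx$tablet_properties$weight_mg, degree = "quadratic"),
    list(y = fx$tablet_properties$hardness_n, degree = "linear"),
    list(y = fx$tablet_properties$drug_load_mg, degree = "quadratic")
  )
  for (cs in cases) {
    fit <- fit_mixture_model(des, cs$y, cs$degree)
    brute <- press_brute_force(des, cs$y, cs$degree)
    expect_equal(press_loo(fit)$press, brute,
                 tolerance = 1e-8 * max(brute, 1),
                 info = cs$degree)
  }
})

test_that("fit statistics are ordered pred <= adj <= r2 on every fixture fit", {
  fx <- builtin_fixtures()
  des <- design_formulations()
  for (y in list(fx$tablet_properties$weight_mg,
                 fx$tablet_properties$hardness_n,
                 fx$tablet_properties$drug_load_mg)) {
    for (d in c("linear", "quadratic", "special_cubic")) {
      fit <- tryCatch(fit_mixture_model(des, y, d),
                      error = function(e) NULL)
      if (is.null(fit)) next
      expect_lte(fit$pred_r2, fit$adj_r2 + 1e-12)
      expect_lte(fit$adj_r2, fit$r2 + 1e-12)
    }
  }
})

test_that("fitted values are invariant to a common rescaling of components", {
  des <- design_formulations()
  y <- builtin_fixtures()$tablet_properties$weight_mg
  fit1 <- fit_mixture_model(des, y, "linear")
  des_frac <- des
  des_frac$pegda <- des$pegda / 100
  des_frac$peg400 <- des$peg400 / 100
  des_frac$water <- des$water / 100
  fit2 <- fit_mixture_model(des_frac, y, "linear")
  expect_equal(fit1$fitted, fit2$fitted, tolerance = 1e-9)
  expect_equal(unname(fit2$coefficients), unname(fit1$coefficients) * 100,
               tolerance = 1e-9)
})

test_that("degrees without residual df are unavailable, not fitted", {
  fx <- builtin_fixtures()
  des <- design_formulations()
  # hardness has 10 usable rows; the 10-term full cubic leaves no residual
  # df and is reported unavailable, while the weight response (n = 11)
  # still supports it
  res <- fit_all_degrees(des, fx$tablet_properties$hardness_n, "hardness")
  expect_false(res$summary$available[res$summary$degree == "full_cubic"])
  expect_true(res$summary$available[res$summary$degree == "linear"])
  res_w <- fit_all_degrees(des, fx$tablet_properties$weight_mg, "weight")
  expect_true(all(res_w$summary$available))
})

test_that("model selection follows joint adjusted/predicted maximization", {
  fx <- builtin_fixtures()
  des <- design_formulations()
  for (y in list(fx$tablet_properties$weight_mg,
                 fx$tablet_properties$hardness_n,
                 fx$tablet_properties$drug_load_mg)) {
    all_fits <- fit_all_degrees(des, y)
    expect_equal(select_model(all_fits$fits)$degree, "linear")
  }

  # single candidate wins by default
  one <- fit_mixture_model(des, fx$tablet_properties$weight_mg, "linear")
  expect_equal(select_model(list(linear = one))$degree, "linear")

  # equal adjusted R2: higher predicted R2 breaks the tie
  a <- one; a$adj_r2 <- 0.5; a$pred_r2 <- 0.3
  b <- one; b$adj_r2 <- 0.5; b$pred_r2 <- 0.4; b$degree <- "quadratic"
  expect_equal(select_model(list(linear = a, quadratic = b))$degree,
               "quadratic")
})

test_that("D-optimal exchange picks vertices on the full simplex and improves monotonically", {
  full <- design_bounds(pegda = c(0, 100), peg400 = c(0, 100),
                        water = c(0, 100), mixture_total = 100,
                        riboflavin = 0, ibuprofen = 0)
  res <- doptimal_design(full, n_runs = 3, degree = "linear",
                         n_candidates = 60, seed = 3)
  pts <- as.matrix(res$design[, c("pegda", "peg400", "water")])
  # the determinant-maximizing 3-run linear design is the three vertices
  expect_equal(sort(apply(pts, 1, max)), c(100, 100, 100))
  expect_true(all(diff(res$log_det_trace) >= -1e-12))
})

test_that("the exchanged design beats random candidate subsets", {
  b <- design_bounds()
  res <- doptimal_design(b, n_runs = 11, degree = "linear",
                         n_candidates = 120, seed = 5)
  cand <- res$candidates
  X_of <- function(rows) {
    t(apply(cand[rows, , drop = FALSE], 1, function(x)
      scheffe_terms(stats::setNames(x, c("pegda", "peg400", "water")),
                    "linear")))
  }
  logdet <- function(X) {
    d <- determinant(crossprod(X), logarithm = TRUE)
    if (d$sign <= 0) -Inf else as.numeric(d$modulus)
  }
  set.seed(5)
  random_vals <- replicate(100, logdet(X_of(sample(nrow(cand), 11))))
  expect_true(all(res$log_det >= random_vals - 1e-9))
  # design points respect the bounds
  expect_true(all(res$design$pegda >= 30 - 1e-9 &
                    res$design$pegda <= 74.6 + 1e-9))
  expect_true(all(res$design$water >= 10 - 1e-9 &
                    res$design$water <= 30 + 1e-9))
  # too few runs for the model is a rank error
  expect_error(doptimal_design(b, n_runs = 2, degree = "linear"),
               "below the number of model terms")
})
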