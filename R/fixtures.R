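#' Built-in reference data for the ibuprofen DLP printlet study
#'
#' Exact transcriptions of the published study tables that the package's
#' worked examples and regression tests are built on: the 15 resin
#' compositions (11 design formulations F1-F11, three external test
#' formulations and a placebo), the per-formulation printing parameters,
#' the measured tablet properties of F1-F11, the published kinetic
#' parameters, and the experimental-versus-predicted release values for the
#' optimized formulation at 2/4/6/8 h.
#'
#' Compositions are stored in percent w/w exactly as printed; row sums fall
#' in 99.7-100.0 because the printed values are rounded to two decimals.
#' The hardness of F7 could not be measured (the tablet was too elastic to
#' break) and is stored as `NA`, never as zero.
#'
#' @return A list with elements:
#' \describe{
#'   \item{formulations}{tibble of 15 compositions (percent w/w): `id`,
#'     `pegda`, `peg400`, `water`, `riboflavin`, `ibuprofen`, and a logical
#'     `design_point` marking F1-F11.}
#'   \item{print_parameters}{tibble of printing settings per formulation:
#'     `exposure_time_s`, `bottom_exposure_s`, `layer_thickness_mm`,
#'     `bottom_layers`.}
#'   \item{tablet_properties}{tibble of measured properties of F1-F11:
#'     `weight_mg`, `diameter_mm`, `thickness_mm`, `hardness_n` (NA for F7),
#'     `drug_load_mg`.}
#'   \item{kinetic_parameters}{tibble of the published kinetic fits (rate
#'     constants per minute) for each formulation plus the optimum.}
#'   \item{optimal_comparison}{tibble with `time_h`, `predicted_nn1`,
#'     `predicted_nn2`, `experimental` (cumulative percent released) for the
#'     optimized formulation.}
#' }
#' @examples
#' fx <- builtin_fixtures()
#' fx$tablet_properties$hardness_n[fx$tablet_properties$id == "F3"]
#' @export
builtin_fixtures <- function() {
  formulations <- tibble::tibble(
    id = c(paste0("F", 1:11), paste0("Test ", 1:3), "F placebo"),
    pegda = c(32.10, 30.00, 74.60, 62.40, 50.60, 65.80, 30.00, 58.10,
              39.30, 46.20, 40.40, 35.00, 55.00, 65.00, 42.50),
    peg400 = c(32.60, 44.10, 10.00, 21.80, 34.00, 11.20, 54.60, 10.00,
               45.30, 23.10, 35.60, 47.90, 24.90, 7.90, 42.40),
    water = c(30.00, 20.50, 10.10, 10.50, 10.00, 17.70, 10.00, 26.60,
              10.00, 25.40, 18.70, 12.00, 15.00, 22.00, 15.00),
    riboflavin = rep(0.10, 15),
    ibuprofen = c(rep(5.00, 14), 0.00),
    design_point = c(rep(TRUE, 11), rep(FALSE, 4))
  )

  print_parameters <- tibble::tibble(
    id = formulations$id,
    exposure_time_s = c(800, 800, 400, 400, 500, 600, 400, 800, 400, 800,
                        600, 400, 500, 600, 600),
    bottom_exposure_s = rep(800, 15),
    layer_thickness_mm = rep(0.10, 15),
    bottom_layers = rep(10L, 15)
  )

  tablet_properties <- tibble::tibble(
    id = paste0("F", 1:11),
    weight_mg = c(387.00, 378.00, 323.40, 296.70, 354.40, 278.90, 345.10,
                  400.10, 340.50, 375.00, 377.50),
    diameter_mm = c(11.13, 10.86, 10.81, 10.17, 10.55, 10.04, 10.52, 12.40,
                    10.60, 11.53, 11.40),
    thickness_mm = c(3.00, 3.09, 3.00, 3.02, 3.00, 3.00, 2.99, 2.97, 2.94,
                     2.92, 2.99),
    hardness_n = c(47.33, 32.00, 108.33, 92.33, 33.00, 132.33, NA, 29.67,
                   19.00, 37.00, 35.00),
    drug_load_mg = c(24.11, 23.00, 15.00, 14.40, 22.30, 18.30, 21.70,
                     27.10, 23.00, 25.80, 25.50)
  )

  kinetic_parameters <- tibble::tibble(
    id = c(paste0("F", 1:11), paste0("Test ", 1:3), "F optimal"),
    k0 = c(0.0707, 0.0643, 0.0614, 0.0727, 0.0997, 0.0744, 0.1445, 0.0510,
           0.0856, 0.0857, 0.1082, 0.1552, 0.1045, 0.0776, 0.1286),
    r2_zero = c(0.9859, 0.9881, 0.9866, 0.9642, 0.9379, 0.9427, 0.9775,
                0.9285, 0.9746, 0.9591, 0.9744, 0.9758, 0.9641, 0.9685,
                0.9892),
    k1 = c(0.0021, 0.0022, 0.0021, 0.0023, 0.0025, 0.0026, 0.0027, 0.0020,
           0.0023, 0.0020, 0.0023, 0.0031, 0.0031, 0.0029, 0.0029),
    r2_first = c(0.9428, 0.9348, 0.9498, 0.8935, 0.8345, 0.8285, 0.8961,
                 0.8493, 0.9089, 0.8963, 0.9089, 0.8732, 0.8563, 0.8875,
                 0.9516),
    kh = c(1.9807, 1.7921, 1.7126, 2.0614, 2.8606, 2.1292, 4.0722, 1.4654,
           2.4164, 2.4347, 3.0557, 4.3715, 2.9500, 2.1940, 3.5609),
    r2_higuchi = c(0.9945, 0.9861, 0.9886, 0.9982, 0.9922, 0.9940, 0.9985,
                   0.9871, 0.9993, 0.9957, 0.9989, 0.9959, 0.9891, 0.9959,
                   0.9749),
    kkp = c(5.3769, 3.9965, 4.5005, 4.1796, 3.9337, 2.3934, 4.7498, 4.0217,
            4.8273, 7.4583, 5.5710, 3.0129, 1.8925, 1.9670, 3.5776),
    r2_kp = c(0.9780, 0.9777, 0.9739, 0.9977, 0.9950, 0.9932, 0.9985,
              0.9962, 0.9972, 0.9968, 0.9958, 0.9980, 0.9944, 0.9969,
              0.9544),
    n = c(0.3588, 0.3843, 0.3619, 0.4024, 0.4609, 0.4895, 0.4767, 0.3671,
          0.4027, 0.3489, 0.4147, 0.5535, 0.5656, 0.5144, 0.4872)
  )

  optimal_comparison <- tibble::tibble(
    time_h = c(2, 4, 6, 8),
    predicted_nn1 = c(41.96, 63.34, 70.00, 79.99),
    predicted_nn2 = c(45.37, 62.77, 76.66, 88.46),
    experimental = c(29.85, 51.18, 65.73, 76.60)
  )

  list(
    formulations = formulations,
    print_parameters = print_parameters,
    tablet_properties = tablet_properties,
    kinetic_parameters = kinetic_parameters,
    optimal_comparison = optimal_comparison
  )
}
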