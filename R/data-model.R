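#' Design bounds for the three-component mixture
#'
#' The variable part of the resin is a constrained three-component mixture
#' of PEGDA (crosslinking monomer), PEG 400 (diluent) and water; riboflavin
#' (photoinitiator) and ibuprofen are held fixed, so the three variable
#' components sum to `mixture_total` percent w/w.
#'
#' @param pegda,peg400,water Numeric length-2 vectors `c(lower, upper)` in
#'   percent w/w.
#' @param mixture_total Sum of the three variable components, percent w/w.
#' @param riboflavin,ibuprofen Fixed component levels, percent w/w.
#' @return An object of class `design_bounds`.
#' @examples
#' design_bounds()
#' @export
design_bounds <- function(pegda = c(30.0, 74.6), peg400 = c(10.0, 54.6),
                          water = c(10.0, 30.0), mixture_total = 94.9,
                          riboflavin = 0.10, ibuprofen = 5.00) {
  for (b in list(pegda, peg400, water)) {
    stopifnot(length(b) == 2, is.numeric(b), b[1] <= b[2], b[1] >= 0)
  }
  structure(
    list(
      lower = c(pegda = pegda[1], peg400 = peg400[1], water = water[1]),
      upper = c(pegda = pegda[2], peg400 = peg400[2], water = water[2]),
      mixture_total = mixture_total,
      riboflavin = riboflavin,
      ibuprofen = ibuprofen
    ),
    class = "design_bounds"
  )
}

#' @export
print.design_bounds <- function(x, ...) {
  cat("Mixture design bounds (% w/w), variable components sum to",
      x$mixture_total, "\n")
  for (nm in names(x$lower)) {
    cat(sprintf("  %-7s [%5.1f, %5.1f]\n", nm, x$lower[[nm]], x$upper[[nm]]))
  }
  cat(sprintf("  fixed: riboflavin %.2f, ibuprofen %.2f\n",
              x$riboflavin, x$ibuprofen))
  invisible(x)
}

component_names <- function() c("pegda", "peg400", "water")

formulation_columns <- function() {
  c("id", "pegda", "peg400", "water", "riboflavin", "ibuprofen")
}

#' Assemble and validate a formulation table
#'
#' @param df A data frame with columns `id`, `pegda`, `peg400`, `water`,
#'   `riboflavin`, `ibuprofen` (compositions in percent w/w).
#' @return A tibble with validated compositions, row order preserved.
#' @details Components must be non-negative and each row must sum to a
#'   value in (99.0, 100.5): published compositions sum to 99.7-100.0
#'   because each entry is rounded to two decimals, so exact-100 row sums
#'   are not required.
#' @export
as_formulation_table <- function(df) {
  missing_cols <- setdiff(formulation_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("formulation table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(df)[, union(formulation_columns(), names(df))]
  num_cols <- setdiff(formulation_columns(), "id")
  for (nm in num_cols) {
    v <- out[[nm]]
    if (!is.numeric(v)) stop("column '", nm, "' must be numeric", call. = FALSE)
    if (any(is.na(v))) stop("column '", nm, "' contains missing values",
                            call. = FALSE)
    if (any(v < 0)) {
      stop("negative composition in column '", nm, "' (row ",
           which(v < 0)[1], ")", call. = FALSE)
    }
  }
  if (nrow(out) > 0) {
    total <- rowSums(out[, num_cols])
    bad <- which(total <= 99.0 | total >= 100.5)
    if (length(bad) > 0) {
      stop("component sum out of (99.0, 100.5) for row ", bad[1],
           " (id ", out$id[bad[1]], "): ", round(total[bad[1]], 3),
           call. = FALSE)
    }
  }
  out
}

#' Read a formulation table from CSV
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param dialect Optional named character vector mapping the canonical
#'   column names (`id`, `pegda`, `peg400`, `water`, `riboflavin`,
#'   `ibuprofen`) to the names used in the file.
#' @return A validated formulation tibble; one record per row, order
#'   preserved. An empty file (header only) gives a zero-row tibble.
#' @export
load_formulation_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (!dialect[[canon]] %in% names(df)) {
        stop("dialect column '", dialect[[canon]], "' not present in file",
             call. = FALSE)
      }
      names(df)[names(df) == dialect[[canon]]] <- canon
    }
  }
  if (nrow(df) == 0) {
    missing_cols <- setdiff(formulation_columns(), names(df))
    if (length(missing_cols) > 0) {
      stop("formulation table is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    df$id <- as.character(df$id)
    return(tibble::as_tibble(df)[, formulation_columns()])
  }
  df$id <- as.character(df$id)
  as_formulation_table(df)
}

#' Write a formulation table to CSV
#'
#' Values are written with enough precision that a write/read round trip is
#' exact at the two-decimal precision compositions are recorded in.
#'
#' @param formulations A formulation tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_formulation_table <- function(formulations, path) {
  utils::write.csv(formulations[, formulation_columns()], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Check one composition against design bounds
#'
#' Violations are returned as data, not raised as errors, so that screening
#' a candidate list never aborts.
#'
#' @param f A one-row formulation (data frame or list with `pegda`,
#'   `peg400`, `water`).
#' @param bounds A [design_bounds()] object.
#' @return A tibble of violations with columns `component`, `bound`
#'   (`"lower"` or `"upper"`), `limit`, `value`; zero rows when the
#'   composition is inside the bounds.
#' @examples
#' validate_formulation(list(pegda = 32.1, peg400 = 32.6, water = 30.0),
#'                      design_bounds())
#' @export
validate_formulation <- function(f, bounds = design_bounds()) {
  comp <- vapply(component_names(), function(nm) as.numeric(f[[nm]]),
                 numeric(1))
  rows <- list()
  for (nm in component_names()) {
    if (comp[[nm]] < bounds$lower[[nm]]) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        component = nm, bound = "lower", limit = bounds$lower[[nm]],
        value = comp[[nm]])
    }
    if (comp[[nm]] > bounds$upper[[nm]]) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        component = nm, bound = "upper", limit = bounds$upper[[nm]],
        value = comp[[nm]])
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(component = character(), bound = character(),
                          limit = numeric(), value = numeric()))
  }
  do.call(rbind, rows)
}

#' Construct a dissolution profile
#'
#' @param times Sampling times in hours, strictly increasing, all > 0.
#' @param released Cumulative percent of the dose released at each time.
#' @param sd Optional per-point replicate standard deviation (percent).
#' @param id Optional profile label.
#' @return An object of class `dissolution_profile`.
#' @details Released values must lie in \[0, 110\]: a small overshoot above
#'   100 percent is tolerated because assayed cumulative release can exceed
#'   the nominal dose within analytical error.
#' @export
dissolution_profile <- function(times, released, sd = NULL, id = NULL) {
  times <- as.numeric(times)
  released <- as.numeric(released)
  if (length(times) != length(released)) {
    stop("times and released must have equal length", call. = FALSE)
  }
  if (length(times) > 0 && (any(times <= 0) || any(diff(times) <= 0))) {
    stop("times must be positive and strictly increasing", call. = FALSE)
  }
  if (any(released < 0 | released > 110)) {
    stop("released values must lie in [0, 110]", call. = FALSE)
  }
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    if (length(sd) != length(times)) {
      stop("sd must match times in length", call. = FALSE)
    }
    if (any(sd < 0, na.rm = TRUE)) stop("sd must be non-negative",
                                        call. = FALSE)
  }
  structure(list(times = times, released = released, sd = sd, id = id),
            class = "dissolution_profile")
}

#' @export
print.dissolution_profile <- function(x, ...) {
  cat("Dissolution profile", if (!is.null(x$id)) paste0("'", x$id, "'"),
      "-", length(x$times), "time points\n")
  print(tibble::tibble(time_h = x$times, released_pct = x$released,
                       sd_pct = if (is.null(x$sd)) NA_real_ else x$sd))
  invisible(x)
}

#' Read dissolution profiles from a long-format CSV
#'
#' @param path CSV with columns `id`, `time_h`, `released_pct` and
#'   optionally `sd_pct`.
#' @return A named list of [dissolution_profile()] objects, one per `id`,
#'   in order of first appearance.
#' @export
load_profile_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  needed <- c("id", "time_h", "released_pct")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("profile table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ids <- unique(as.character(df$id))
  out <- lapply(ids, function(i) {
    sub <- df[as.character(df$id) == i, , drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    dissolution_profile(sub$time_h, sub$released_pct,
                        sd = if ("sd_pct" %in% names(sub)) sub$sd_pct,
                        id = i)
  })
  names(out) <- ids
  out
}

#' Write dissolution profiles to a long-format CSV
#'
#' @param profiles A list of [dissolution_profile()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(id = if (is.null(p$id)) NA_character_ else p$id,
               time_h = p$times, released_pct = p$released,
               sd_pct = if (is.null(p$sd)) NA_real_ else p$sd)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tablet-properties table from CSV
#'
#' @param path CSV with columns `id`, `weight_mg`, `diameter_mm`,
#'   `thickness_mm`, `hardness_n`, `drug_load_mg`. Unmeasured values (for
#'   example a hardness that could not be determined) are empty cells or
#'   `NA`, never zero.
#' @return A tibble; all present numeric values are checked to be positive.
#' @export
load_properties_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  needed <- c("id", "weight_mg", "diameter_mm", "thickness_mm",
              "hardness_n", "drug_load_mg")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("properties table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (nm in setdiff(needed, "id")) {
    v <- df[[nm]]
    if (any(v <= 0, na.rm = TRUE)) {
      stop("non-positive value in column '", nm, "'", call. = FALSE)
    }
  }
  df$id <- as.character(df$id)
  tibble::as_tibble(df)[, needed]
}
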