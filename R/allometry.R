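# Allometric regressions on the species table: vocal fold length and f0
# bounds versus body mass (power laws, fitted on log10-log10 scale) and
# the stiffness exponent B versus vocal fold length (ordinary linear
# scale). Plain OLS throughout, matching the comparative analysis being
# reproduced; no phylogenetic correction.

#' Average male and female records per species
#'
#' The cross-species regressions treat a species as one point. Under
#' `policy = "average"`, species measured in both sexes are collapsed to a
#' single record with the arithmetic mean of each numeric trait over the
#' sexes in which it was measured; under `policy = "separate"` records
#' pass through unchanged.
#'
#' @param table a `species_table`.
#' @param policy `"average"` (default) or `"separate"`.
#' @return A `species_table` with one record per species (`average`) or
#'   the input (`separate`).
#' @examples
#' tab <- load_species_table()
#' avg <- aggregate_sexes(tab)
#' avg[avg$species == "Human", c("body_mass_kg", "l0_mm")]  # 67.5 kg, 13 mm
#' @export
aggregate_sexes <- function(table, policy = c("average", "separate")) {
  stopifnot(inherits(table, "species_table"))
  policy <- match.arg(policy)
  if (policy == "separate") return(table)
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  pieces <- lapply(unique(table$species), function(sp) {
    rows <- table[table$species == sp, , drop = FALSE]
    if (nrow(rows) == 1) return(rows)
    out <- rows[1, , drop = FALSE]
    out$sex <- "unspecified"
    for (col in NUMERIC_COLUMNS) out[[col]] <- mean_or_na(rows[[col]])
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  structure(out, provenance = attr(table, "provenance"),
            class = c("species_table", "data.frame"))
}

new_allometric_fit <- function(kind, coefficient, exponent, r_squared,
                               p_value, n, excluded = character()) {
  structure(list(kind = kind, coefficient = coefficient, exponent = exponent,
                 r_squared = r_squared, p_value = p_value, n = n,
                 excluded = excluded),
            class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  if (x$kind == "power_law") {
    cat(sprintf("<allometric_fit> y = %.4g * x^%.4g\n", x$coefficient, x$exponent))
  } else {
    cat(sprintf("<allometric_fit> y = %.4g + %.4g * x\n", x$coefficient, x$exponent))
  }
  cat(sprintf("  r^2 = %.3f, p = %.3g, n = %d\n", x$r_squared, x$p_value, x$n))
  if (length(x$excluded) > 0) {
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit a power law y = a * x^b
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`; the coefficient is
#' back-transformed (`a = 10^intercept`). The p-value is the two-sided
#' t-test on the slope with n - 2 degrees of freedom.
#'
#' @param x,y positive numeric vectors of equal length, n >= 3. Pairs with
#'   a missing value are dropped (count reported via `excluded`).
#' @param labels optional record labels used to report dropped rows.
#' @return An `allometric_fit` with `kind = "power_law"`.
#' @export
fit_power_law <- function(x, y, labels = NULL) {
  keep <- !is.na(x) & !is.na(y)
  excluded <- if (is.null(labels)) {
    if (any(!keep)) sprintf("%d record(s) with missing values", sum(!keep)) else character()
  } else labels[!keep]
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y)) abort_domain("`x` and `y` must have equal length")
  if (length(x) < 3) abort_domain("power-law fit needs at least 3 complete pairs")
  if (any(x <= 0) || any(y <= 0)) {
    abort_domain("power-law fit requires strictly positive `x` and `y`")
  }
  fit <- stats::lm(log10(y) ~ log10(x))
  # suppress the "essentially perfect fit" note: exact power laws are a
  # legitimate input (noiseless synthetic tables)
  sm <- suppressWarnings(summary(fit))
  new_allometric_fit(
    kind = "power_law",
    coefficient = 10^unname(stats::coef(fit)[1]),
    exponent = unname(stats::coef(fit)[2]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    n = length(x),
    excluded = excluded
  )
}

#' Fit a straight line y = a + b * x
#'
#' Ordinary least squares on the original scale. Used for the stiffness
#' exponent B versus vocal fold length L0, where the relation (if any) is
#' additive, not multiplicative.
#'
#' @inheritParams fit_power_law
#' @return An `allometric_fit` with `kind = "linear"`; `coefficient` is
#'   the intercept and `exponent` the slope.
#' @export
fit_linear <- function(x, y, labels = NULL) {
  keep <- !is.na(x) & !is.na(y)
  excluded <- if (is.null(labels)) {
    if (any(!keep)) sprintf("%d record(s) with missing values", sum(!keep)) else character()
  } else labels[!keep]
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y)) abort_domain("`x` and `y` must have equal length")
  if (length(x) < 3) abort_domain("linear fit needs at least 3 complete pairs")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  # constant y: define r^2 = 0 and p = 1 rather than NaN
  r2 <- if (stats::var(y) == 0) 0 else sm$r.squared
  p <- if (stats::var(y) == 0) 1 else sm$coefficients[2, 4]
  new_allometric_fit(
    kind = "linear",
    coefficient = unname(stats::coef(fit)[1]),
    exponent = unname(stats::coef(fit)[2]),
    r_squared = r2,
    p_value = p,
    n = length(x),
    excluded = excluded
  )
}

#' Vocal fold length versus body mass
#'
#' The length-mass allometry: a power-law fit of cadaveric vocal fold
#' length `L0` (mm) on body mass (kg). On the packaged table with sexes
#' averaged (16 species, bat to elephant) the fit is
#' `L0 ~ 3.2 * M^0.40`, r^2 ~ 0.97.
#'
#' @param table a `species_table`.
#' @param policy sex-handling policy, see [aggregate_sexes()].
#' @return An `allometric_fit`.
#' @export
fit_length_mass <- function(table, policy = c("average", "separate")) {
  tab <- aggregate_sexes(table, match.arg(policy))
  fit_power_law(tab$body_mass_kg, tab$l0_mm,
                labels = paste(tab$species, tab$sex))
}

#' f0 bounds versus body mass
#'
#' Power-law fits of the upper (`fo2`) and lower (`fo1`) fundamental
#' frequency bounds on body mass, over records with a printed f0 range.
#' Both slopes are negative: larger species phonate lower. The two fits
#' are re-estimated from the table, not asserted from published
#' coefficients.
#'
#' @inheritParams fit_length_mass
#' @return List with elements `fo2` and `fo1`, each an `allometric_fit`.
#' @export
fit_fo_bounds <- function(table, policy = c("average", "separate")) {
  tab <- aggregate_sexes(table, match.arg(policy))
  tab <- filter_records(tab, has_fo_range = TRUE)
  if (nrow(tab) < 3) abort_domain("fewer than 3 records with both f0 bounds")
  labels <- paste(tab$species, tab$sex)
  list(fo2 = fit_power_law(tab$body_mass_kg, tab$fo2_hz, labels = labels),
       fo1 = fit_power_law(tab$body_mass_kg, tab$fo1_hz, labels = labels))
}

#' Stiffness exponent B versus vocal fold length
#'
#' Linear fit of the stress-strain exponent `B` on cadaveric length `L0`
#' over the sex-specific records with a measured stress law. The rhesus
#' monkey carries extreme `B` values (16.2 male, 12.9 female) and is
#' excluded by default as the outlier; with it included the mild positive
#' trend disappears (slope p-value well above 0.05).
#'
#' @param table a `species_table`.
#' @param include_rhesus include the rhesus monkey records (default FALSE).
#' @return An `allometric_fit` (linear); `excluded` names dropped records.
#' @export
fit_b_length <- function(table, include_rhesus = FALSE) {
  tab <- filter_records(table, has_stress_law = TRUE)
  dropped <- character()
  if (!include_rhesus) {
    is_rhesus <- grepl("rhesus", tab$species, ignore.case = TRUE)
    dropped <- paste(tab$species[is_rhesus], tab$sex[is_rhesus])
    tab <- tab[!is_rhesus, , drop = FALSE]
  }
  fit <- fit_linear(tab$l0_mm, tab$stress_B,
                    labels = paste(tab$species, tab$sex))
  fit$excluded <- c(fit$excluded, dropped)
  fit
}

#' Predict from an allometric fit
#'
#' @param fit an `allometric_fit`.
#' @param x predictor values (positive for power laws).
#' @return Predicted response: `coefficient * x^exponent` for power laws,
#'   `coefficient + exponent * x` for linear fits.
#' @export
predict_from_fit <- function(fit, x) {
  stopifnot(inherits(fit, "allometric_fit"))
  if (fit$kind == "power_law") {
    if (any(x <= 0)) abort_domain("power-law prediction requires positive `x`")
    fit$coefficient * x^fit$exponent
  } else {
    fit$coefficient + fit$exponent * x
  }
}

#' Export a fit as a JSON-ready list
#'
#' @param fit an `allometric_fit`.
#' @return A plain list suitable for `jsonlite::toJSON()`.
#' @export
fit_to_list <- function(fit) {
  stopifnot(inherits(fit, "allometric_fit"))
  list(kind = fit$kind, coefficient = fit$coefficient,
       exponent = fit$exponent, r_squared = fit$r_squared,
       p_value = fit$p_value, n = fit$n,
       excluded = as.character(fit$excluded))
}
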