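# Inverse and exploratory operations on the (B, L2/L1) morphospace of
# achievable fundamental frequency range. The achievable range is a
# surface over two morphological variables: the stiffness exponent B of
# the tissue and the elongation ratio L2/L1 permitted by the laryngeal
# framework; different morphologies can reach the same range.

#' Achievable f0 range in octaves
#'
#' Evaluates the string-model frequency ratio on the morphospace
#' parameterization: `L1 = l1_fraction * L0`, `L2 = length_ratio * L1`,
#' and returns the range as `log2(fo2/fo1)`.
#'
#' @param B dimensionless stiffness exponent; >= 0.
#' @param length_ratio elongation ratio `L2/L1`; >= 1.
#' @param l1_fraction shortest phonatory length as a fraction of the
#'   cadaveric length `L0`; default 0.7 as measured in humans.
#' @return Achievable range in octaves (negative if the length penalty
#'   outweighs the stress gain).
#' @examples
#' achievable_octaves(B = 10, length_ratio = 2)    # ~4 octaves
#' achievable_octaves(B = 10, length_ratio = 1.5)  # ~2 octaves
#' @export
achievable_octaves <- function(B, length_ratio, l1_fraction = 0.7) {
  check_scalar(B, "B")
  if (B < 0) abort_domain(sprintf("`B` must be >= 0 (got %g)", B))
  check_scalar(length_ratio, "length_ratio")
  if (length_ratio < 1) {
    abort_domain(sprintf("`length_ratio` must be >= 1 (got %g)", length_ratio))
  }
  check_positive(l1_fraction, "l1_fraction")
  # log2 of (L2/L1)^-1 * exp(B/2 * (L2-L1)/L0), with (L2-L1)/L0 =
  # l1_fraction * (length_ratio - 1)
  (-log(length_ratio) + 0.5 * B * l1_fraction * (length_ratio - 1)) / log(2)
}

#' Stiffness exponent required for a target f0 ratio
#'
#' Closed-form inversion of the string model for `B` given the elongation
#' ratio and a target `fo2/fo1`:
#' `B = 2 * ln(target_ratio * length_ratio) / (l1_fraction * (length_ratio - 1))`.
#'
#' If `target_ratio * length_ratio <= 1` the target is reachable on length
#' change alone and the returned `B` is negative; it is flagged with the
#' attribute `infeasible_for_fibrous_gain` (no fibrous stress gain needed).
#'
#' @param length_ratio elongation ratio `L2/L1`; must be > 1.
#' @param target_ratio target `fo2/fo1`; > 0.
#' @inheritParams achievable_octaves
#' @return The required `B` (dimensionless).
#' @examples
#' required_B(length_ratio = 1.7, target_ratio = 5)  # ~8.7, human male range
#' @export
required_B <- function(length_ratio, target_ratio, l1_fraction = 0.7) {
  check_scalar(length_ratio, "length_ratio")
  if (length_ratio <= 1) {
    abort_domain("`length_ratio` must be > 1: elongation is required to solve for B")
  }
  check_positive(target_ratio, "target_ratio")
  check_positive(l1_fraction, "l1_fraction")
  B <- 2 * log(target_ratio * length_ratio) / (l1_fraction * (length_ratio - 1))
  if (B < 0) attr(B, "infeasible_for_fibrous_gain") <- TRUE
  B
}

#' Elongation ratio required for a target f0 ratio
#'
#' Solves `fo2/fo1(x) = target_ratio` for the elongation ratio
#' `x = L2/L1` by bracketed root finding on `[1, 10]`.
#'
#' The frequency ratio `exp(c*(x-1))/x` with `c = B*l1_fraction/2` is
#' strictly increasing on `x >= 1` only when `c > 1/x` throughout, i.e.
#' `B > 2/l1_fraction` (about 2.86 at the default 0.7). Below that bound
#' the surface is non-monotone and the operation refuses rather than
#' silently picking a branch.
#'
#' @param B dimensionless stiffness exponent; must exceed `2/l1_fraction`.
#' @param target_ratio target `fo2/fo1`; > 1.
#' @inheritParams achievable_octaves
#' @param tol absolute tolerance of the root, default 1e-9 so that the
#'   round-trip through [achievable_octaves()] holds to 1e-6 octaves even
#'   where the surface is steep.
#' @return The elongation ratio `L2/L1` in `[1, 10]`.
#' @examples
#' required_length_ratio(B = 16.2, target_ratio = 16)  # ~1.6, male rhesus
#' required_length_ratio(B = 8.5, target_ratio = 16)   # ~2.2, tiger
#' @export
required_length_ratio <- function(B, target_ratio, l1_fraction = 0.7,
                                  tol = 1e-9) {
  check_scalar(B, "B")
  check_positive(target_ratio, "target_ratio")
  if (target_ratio <= 1) {
    abort_domain("`target_ratio` must be > 1 (a range, not a contraction)")
  }
  check_positive(l1_fraction, "l1_fraction")
  bound <- 2 / l1_fraction
  if (B <= bound) {
    abort_domain(sprintf(
      "`B` = %g is at or below the monotonicity bound 2/l1_fraction = %g; the frequency-ratio surface is non-monotone in the length ratio there and the inversion is not unique",
      B, bound))
  }
  lo <- 1 + 1e-9
  hi <- 10
  target_oct <- log2(target_ratio)
  f <- function(x) achievable_octaves(B, x, l1_fraction) - target_oct
  if (f(lo) > 0 || f(hi) < 0) {
    abort_infeasible(sprintf(
      "no elongation ratio in [1, 10] reaches fo2/fo1 = %g at B = %g", target_ratio, B))
  }
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Grid of achievable octave range over the (B, L2/L1) morphospace
#'
#' Evaluates [achievable_octaves()] on the outer product of a vector of
#' `B` values (rows) and a vector of elongation ratios (columns), the
#' surface underlying the range contour plot.
#'
#' @param b_values ascending vector of stiffness exponents.
#' @param ratio_values ascending vector of elongation ratios (>= 1).
#' @inheritParams achievable_octaves
#' @return An object of class `morphospace_grid`: list with `b_values`,
#'   `ratio_values`, `l1_fraction` and the `octave_surface` matrix
#'   (rows = B, columns = L2/L1).
#' @export
morphospace_grid <- function(b_values, ratio_values, l1_fraction = 0.7) {
  if (length(b_values) < 1 || length(ratio_values) < 1) {
    abort_domain("both grid axes must be non-empty")
  }
  if (is.unsorted(b_values, strictly = TRUE)) {
    abort_domain("`b_values` must be sorted strictly ascending")
  }
  if (is.unsorted(ratio_values, strictly = TRUE)) {
    abort_domain("`ratio_values` must be sorted strictly ascending")
  }
  surface <- outer(b_values, ratio_values,
                   Vectorize(function(b, x) achievable_octaves(b, x, l1_fraction)))
  dimnames(surface) <- list(B = as.character(b_values),
                            ratio = as.character(ratio_values))
  structure(list(b_values = b_values, ratio_values = ratio_values,
                 l1_fraction = l1_fraction, octave_surface = surface),
            class = "morphospace_grid")
}

#' @export
print.morphospace_grid <- function(x, ...) {
  cat(sprintf("<morphospace_grid> %d B values x %d length ratios, L1 = %g*L0\n",
              length(x$b_values), length(x$ratio_values), x$l1_fraction))
  cat(sprintf("octave range: %.2f to %.2f\n",
              min(x$octave_surface), max(x$octave_surface)))
  invisible(x)
}

#' Write a morphospace grid as CSV
#'
#' Header row carries the L2/L1 axis, the first column the B axis, cells
#' the achievable range in octaves.
#'
#' @param grid a [morphospace_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "morphospace_grid"))
  df <- data.frame(B = grid$b_values, grid$octave_surface,
                   check.names = FALSE)
  names(df) <- c("B", as.character(grid$ratio_values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Place species on the morphospace for a stated octave target
#'
#' For each record with a measured stress law, computes the elongation
#' ratio that would be required to reach `target_octaves` at that
#' species' `B` value — the horizontal coordinate of the species overlay
#' on the range contour plot.
#'
#' @param table a species table (see [load_species_table()]).
#' @param target_octaves the octave target, default 4.
#' @inheritParams achievable_octaves
#' @return Data frame with species, sex, stress_B and required_ratio
#'   (NA where `B` is at or below the monotonicity bound or the target is
#'   out of bracket).
#' @export
place_species <- function(table, target_octaves = 4, l1_fraction = 0.7) {
  df <- as.data.frame(table)
  df <- df[!is.na(df$stress_B), , drop = FALSE]
  ratio <- vapply(df$stress_B, function(b) {
    tryCatch(required_length_ratio(b, 2^target_octaves, l1_fraction),
             error = function(e) NA_real_)
  }, numeric(1))
  data.frame(species = df$species, sex = df$sex, stress_B = df$stress_B,
             required_ratio = ratio, stringsAsFactors = FALSE)
}
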