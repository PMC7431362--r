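#' Distance bin grid
#'
#' Defines the half-open distance bins \eqn{[k w, (k+1) w)} on which all
#' frequency tables and potentials are tabulated. Defaults are 0.5 Angstrom
#' bins up to a 15.0 Angstrom cutoff (30 bins).
#'
#' @param bin_width Bin width in Angstrom.
#' @param cutoff Upper distance cutoff in Angstrom (exclusive). Must be an
#'   integer multiple of `bin_width`.
#' @return An object of class `bin_grid` with elements `bin_width`, `cutoff`,
#'   `n_bins`, `centers` (bin midpoints), `breaks`.
#' @examples
#' g <- bin_grid()
#' g$n_bins        # 30
#' g$centers[1:3]  # 0.25 0.75 1.25
#' @export
bin_grid <- function(bin_width = 0.5, cutoff = 15.0) {
  stopifnot(bin_width > 0, cutoff > 0)
  n_bins <- cutoff / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("cutoff must be an integer multiple of bin_width")
  n_bins <- as.integer(round(n_bins))
  structure(list(
    bin_width = bin_width,
    cutoff = cutoff,
    n_bins = n_bins,
    centers = (seq_len(n_bins) - 0.5) * bin_width,
    breaks = seq(0, cutoff, by = bin_width)
  ), class = "bin_grid")
}

#' Map distances to bin indices
#'
#' @param d Numeric vector of distances in `[0, cutoff)`.
#' @param grid A [bin_grid()].
#' @return Integer bin indices in `1..n_bins`; `NA` for distances outside the
#'   grid support.
#' @export
bin_index <- function(d, grid) {
  idx <- floor(d / grid$bin_width) + 1L
  idx[d < 0 | d >= grid$cutoff] <- NA_integer_
  as.integer(idx)
}
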