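#' Collect qualifying distances over a corpus, grouped by pair type
#'
#' Concatenates [qualifying_pairs()] over all chains of a corpus and groups
#' the raw (unbinned) distances by canonical pair-type key. Raw values are
#' kept because frequencies are later estimated by kernel density estimation,
#' not by histogramming.
#'
#' @param corpus List of [structure_model()] objects.
#' @param min_separation Minimum residue separation (default 4).
#' @param grid A [bin_grid()]; its cutoff bounds the collected distances.
#' @return Named list mapping pair-type key to a numeric vector of distances.
#' @export
collect_distances <- function(corpus, min_separation = 4, grid = bin_grid()) {
  if (length(corpus) == 0) stop("empty corpus")
  parts <- lapply(corpus, qualifying_pairs,
                  min_separation = min_separation, cutoff = grid$cutoff)
  all <- do.call(rbind, parts)
  if (is.null(all) || nrow(all) == 0) return(list())
  split(all$distance, all$key)
}

scott_bandwidth <- function(d) {
  n <- length(d)
  s <- stats::sd(d)
  iq <- stats::IQR(d) / 1.349
  spread <- min(s, if (iq > 0) iq else s)
  1.06 * spread * n^(-1 / 5)
}

#' Estimate binned frequencies of a distance sample by Gaussian KDE
#'
#' A Gaussian kernel density with a Scott rule-of-thumb bandwidth
#' \eqn{h = 1.06 \min(sd, IQR/1.349) n^{-1/5}} is integrated exactly over
#' each bin (differences of the Gaussian CDF), then renormalized to sum
#' exactly 1 over the `[0, cutoff)` support (mass leaking past the cutoff is
#' discarded by the renormalization). As the bandwidth shrinks the estimate
#' converges to the plain histogram. Degenerate samples (zero spread) put
#' mass 1 in the single occupied bin; samples of fewer than two observations
#' are flagged insufficient (all-zero vector with attribute `insufficient`).
#'
#' @param d Numeric vector of distances in `[0, cutoff)`.
#' @param grid A [bin_grid()].
#' @param bandwidth Optional bandwidth override (Angstrom); `NULL` uses the
#'   Scott rule.
#' @return Numeric vector of `n_bins` frequencies summing to 1 (or all-zero
#'   with `attr(, "insufficient") = TRUE`).
#' @export
estimate_frequencies <- function(d, grid = bin_grid(), bandwidth = NULL) {
  f <- numeric(grid$n_bins)
  if (length(d) < 2)
    return(structure(f, insufficient = TRUE))
  if (any(d < 0 | d >= grid$cutoff))
    stop("all distances must lie in [0, cutoff)")
  h <- if (is.null(bandwidth)) scott_bandwidth(d) else bandwidth
  if (!is.finite(h) || h <= 0) {
    f[bin_index(d[1], grid)] <- 1
    return(f)
  }
  # kernel mass per bin: differences of the Gaussian CDF, chunked to bound
  # memory
  n <- length(d)
  mass <- numeric(grid$n_bins + 1L)
  step <- 100000L
  for (lo in seq(1L, n, by = step)) {
    hi <- min(lo + step - 1L, n)
    z <- outer(grid$breaks, d[lo:hi], "-") / h
    mass <- mass + rowSums(stats::pnorm(z))
  }
  f <- diff(mass) / n
  s <- sum(f)
  if (s <= 0) {
    f[bin_index(stats::median(d), grid)] <- 1
    return(f)
  }
  f / s
}

#' Reference state: count-weighted mean of per-pair frequency vectors
#'
#' The reference distribution is the weighted arithmetic mean of all
#' per-pair-type observed distributions, weighting each by its raw number of
#' distance observations. This equals the pooled, type-indistinct distance
#' distribution when all pair types share one bandwidth. Pairs flagged
#' insufficient are excluded.
#'
#' @param per_pair Named list; each element a list with `freq` (n_bins
#'   frequencies) and `count` (number of raw observations).
#' @return Numeric vector of `n_bins` reference frequencies summing to 1.
#' @export
build_reference <- function(per_pair) {
  usable <- Filter(function(p) p$count > 0 && !isTRUE(attr(p$freq, "insufficient")),
                   per_pair)
  if (length(usable) == 0) stop("no usable pair types to build a reference")
  counts <- vapply(usable, function(p) p$count, numeric(1))
  fmat <- vapply(usable, function(p) as.numeric(p$freq),
                 numeric(length(usable[[1]]$freq)))
  as.numeric(fmat %*% counts) / sum(counts)
}

#' Train a frequency table from a corpus of native chains
#'
#' Runs the full training pipeline: qualifying-pair enumeration over the
#' corpus, per-pair-type KDE frequency estimation, and reference-state
#' construction. Deterministic for fixed inputs.
#'
#' @param corpus List of [structure_model()] objects (native chains).
#' @param selection Atom selection applied to every chain before counting.
#' @param min_separation Minimum residue separation (default 4).
#' @param grid A [bin_grid()].
#' @param min_count Pair types with fewer raw observations than this are
#'   flagged insufficient: excluded from the reference and never scored.
#' @param bandwidth_rule Bandwidth selection rule; only `"scott"`.
#' @return An object of class `frequency_table`: list with `grid`, `per_pair`
#'   (named list of `freq`/`count`/`insufficient`), `reference`,
#'   `total_count`, `params`.
#' @export
train_frequency_table <- function(corpus,
                                  selection = c("all_heavy", "ca_only"),
                                  min_separation = 4,
                                  grid = bin_grid(),
                                  min_count = 2,
                                  bandwidth_rule = c("scott")) {
  selection <- match.arg(selection)
  bandwidth_rule <- match.arg(bandwidth_rule)
  if (length(corpus) == 0) stop("empty corpus")
  corpus <- lapply(corpus, select_atoms, selection = selection)
  dists <- collect_distances(corpus, min_separation = min_separation,
                             grid = grid)
  if (length(dists) == 0) stop("no qualifying pairs in corpus")
  per_pair <- lapply(dists, function(d) {
    cnt <- length(d)
    if (cnt < min_count) {
      freq <- structure(numeric(grid$n_bins), insufficient = TRUE)
    } else {
      freq <- estimate_frequencies(d, grid)
    }
    list(freq = freq, count = cnt,
         insufficient = isTRUE(attr(freq, "insufficient")))
  })
  per_pair <- per_pair[order(names(per_pair))]
  reference <- build_reference(per_pair)
  structure(list(
    grid = grid,
    per_pair = per_pair,
    reference = reference,
    total_count = sum(vapply(per_pair, `[[`, numeric(1), "count")),
    params = list(selection = selection, min_separation = min_separation,
                  min_count = min_count, bandwidth_rule = bandwidth_rule)
  ), class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  ins <- sum(vapply(x$per_pair, `[[`, logical(1), "insufficient"))
  cat(sprintf(paste0("<frequency_table> %d pair types (%d insufficient), ",
                     "%d observations\n  bins: %d x %.2f A, cutoff %.1f A, ",
                     "min_separation %d, selection %s\n"),
              length(x$per_pair), ins, x$total_count, x$grid$n_bins,
              x$grid$bin_width, x$grid$cutoff, x$params$min_separation,
              x$params$selection))
  invisible(x)
}
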