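# Per-bin score terms for the four formalisms. All are vectorized over
# (f_obs, f_ref) and return the default value +10 only where the formula is
# genuinely undefined. Lower total score = more native-like for all four.

DEFAULT_UNDEFINED <- 10

#' Potential-of-mean-force score term
#'
#' The classical inverse-Boltzmann term \eqn{-kT \ln(f_{obs}/f_{ref})} with
#' kT = 1. The logarithm is undefined when either frequency is zero; both
#' cases return the default value +10.
#'
#' @param f_obs,f_ref Observed and reference frequencies in `[0, 1]`.
#' @return Numeric score term(s).
#' @export
pmf_term <- function(f_obs, f_ref) {
  out <- ifelse(f_ref == 0 | f_obs == 0,
                DEFAULT_UNDEFINED,
                -log(f_obs / f_ref))
  as.numeric(out)
}

#' Information-gain score term
#'
#' The relative frequency difference \eqn{-(f_{obs} - f_{ref})/f_{ref}}:
#' the per-bin summand of the total information gain (TIG) score. Defined for
#' `f_obs = 0` (value exactly +1: a distance never seen for this pair type
#' but present in the reference); only `f_ref = 0` is undefined and returns
#' the default +10 (a distance never seen at all in native structures).
#'
#' @inheritParams pmf_term
#' @return Numeric score term(s).
#' @export
tig_term <- function(f_obs, f_ref) {
  out <- ifelse(f_ref == 0, DEFAULT_UNDEFINED, -(f_obs - f_ref) / f_ref)
  as.numeric(out)
}

#' Mock score term 1 (arithmetic-mean denominator)
#'
#' Control formalism dividing the frequency difference by the arithmetic mean
#' of the two frequencies. Undefined only at `f_obs = f_ref = 0` (default
#' +10); at `f_obs = 0, f_ref > 0` the formula itself yields +2.
#'
#' @inheritParams pmf_term
#' @return Numeric score term(s).
#' @export
mck1_term <- function(f_obs, f_ref) {
  out <- ifelse(f_obs == 0 & f_ref == 0,
                DEFAULT_UNDEFINED,
                -(f_obs - f_ref) / ((f_obs + f_ref) / 2))
  as.numeric(out)
}

#' Mock score term 2 (max denominator)
#'
#' Control formalism dividing the frequency difference by the larger of the
#' two frequencies. Undefined only at `f_obs = f_ref = 0` (default +10); at
#' `f_obs = 0, f_ref > 0` the formula yields +1.
#'
#' @inheritParams pmf_term
#' @return Numeric score term(s).
#' @export
mck2_term <- function(f_obs, f_ref) {
  out <- ifelse(f_obs == 0 & f_ref == 0,
                DEFAULT_UNDEFINED,
                -(f_obs - f_ref) / pmax(f_obs, f_ref))
  as.numeric(out)
}

score_term_fun <- function(formalism) {
  switch(formalism,
         PMF = pmf_term, TIG = tig_term, MCK1 = mck1_term, MCK2 = mck2_term,
         stop("unknown formalism: ", formalism))
}

#' Logarithmic mean
#'
#' \eqn{L(x, y) = (x - y)/(\ln x - \ln y)} for positive x, y, with
#' \eqn{L(x, x) = x}. This is the mean implicitly dividing the frequency
#' difference in the PMF formalism: \eqn{-\ln(x/y) = -(x - y)/L(x, y)}.
#'
#' @param x,y Positive numeric vectors.
#' @return Numeric vector of logarithmic means.
#' @export
log_mean <- function(x, y) {
  stopifnot(all(x > 0), all(y > 0))
  ifelse(x == y, x, (x - y) / (log(x) - log(y)))
}

#' Build a potential table from a frequency table
#'
#' Applies the chosen formalism's score term bin-wise to every pair type,
#' against the table's reference distribution. Pair types flagged
#' insufficient are omitted.
#'
#' @param ft A `frequency_table`.
#' @param formalism One of `"PMF"`, `"TIG"`, `"MCK1"`, `"MCK2"`.
#' @return An object of class `potential_table`: list with `grid`,
#'   `formalism`, `terms` (matrix, pair types x bins), `reference`,
#'   `default_undefined`, `kT`, `params`.
#' @export
build_potential <- function(ft, formalism = c("TIG", "PMF", "MCK1", "MCK2")) {
  formalism <- match.arg(formalism)
  term <- score_term_fun(formalism)
  keep <- !vapply(ft$per_pair, `[[`, logical(1), "insufficient")
  pp <- ft$per_pair[keep]
  terms <- t(vapply(pp, function(p) term(as.numeric(p$freq), ft$reference),
                    numeric(ft$grid$n_bins)))
  rownames(terms) <- names(pp)
  structure(list(
    grid = ft$grid,
    formalism = formalism,
    terms = terms,
    reference = ft$reference,
    default_undefined = DEFAULT_UNDEFINED,
    kT = 1,
    params = ft$params
  ), class = "potential_table")
}

#' @export
print.potential_table <- function(x, ...) {
  cat(sprintf("<potential_table> %s: %d pair types x %d bins (%s selection)\n",
              x$formalism, nrow(x$terms), x$grid$n_bins, x$params$selection))
  invisible(x)
}

#' Score a structure with a trained potential
#'
#' Sums the per-bin score term over every qualifying atom pair of the model.
#' Pairs whose pair type is absent from the potential (unseen or flagged
#' insufficient at training) contribute 0 and are counted as skipped:
#' missing coverage is not treated as evidence of non-nativeness. Lower
#' total = more native-like.
#'
#' @param model A [structure_model()].
#' @param potential A `potential_table`.
#' @param selection Atom selection; defaults to the potential's training
#'   selection. A mismatch triggers a warning.
#' @param min_separation Minimum residue separation; defaults to the
#'   potential's training value. A mismatch triggers a warning.
#' @param normalized Also report the per-pair-normalized score.
#' @return One-row data.frame: `model`, `formalism`, `total_score`,
#'   `n_pairs_scored`, `n_pairs_skipped` (and `score_per_pair` if
#'   `normalized`).
#' @export
score_structure <- function(model, potential, selection = NULL,
                            min_separation = NULL, normalized = FALSE) {
  if (is.null(selection)) selection <- potential$params$selection
  else if (selection != potential$params$selection)
    warning("selection differs from the potential's training selection")
  if (is.null(min_separation)) min_separation <- potential$params$min_separation
  else if (min_separation != potential$params$min_separation)
    warning("min_separation differs from the potential's training value")
  sel <- select_atoms(model, selection)
  if (nrow(sel$atoms) == 0) stop("model empty after atom selection")
  pairs <- qualifying_pairs(sel, min_separation = min_separation,
                            cutoff = potential$grid$cutoff)
  if (nrow(pairs) == 0) {
    out <- data.frame(model = model$identifier,
                      formalism = potential$formalism,
                      total_score = 0, n_pairs_scored = 0L,
                      n_pairs_skipped = 0L, stringsAsFactors = FALSE)
    if (normalized) out$score_per_pair <- NA_real_
    return(out)
  }
  ridx <- match(pairs$key, rownames(potential$terms))
  bins <- bin_index(pairs$distance, potential$grid)
  found <- !is.na(ridx)
  total <- sum(potential$terms[cbind(ridx[found], bins[found])])
  out <- data.frame(
    model = model$identifier,
    formalism = potential$formalism,
    total_score = total,
    n_pairs_scored = sum(found),
    n_pairs_skipped = sum(!found),
    stringsAsFactors = FALSE
  )
  if (normalized)
    out$score_per_pair <- if (any(found)) total / sum(found) else NA_real_
  out
}

#' Distance score profile of one pair type
#'
#' @param potential A `potential_table`.
#' @param key Pair-type key, either canonical (`"CYS:CA|CYS:CA"`) or
#'   comma-separated (`"CYS:CA,CYS:CA"`).
#' @return data.frame with columns `bin_center` (Angstrom) and `score`,
#'   one row per bin.
#' @export
score_profile <- function(potential, key) {
  key <- normalize_pair_key(key)
  if (!key %in% rownames(potential$terms)) {
    avail <- rownames(potential$terms)
    near <- utils::head(avail[order(utils::adist(key, avail))], 5)
    stop("pair type not in potential: '", key, "'. Nearest available: ",
         paste(near, collapse = ", "))
  }
  data.frame(bin_center = potential$grid$centers,
             score = as.numeric(potential$terms[key, ]))
}

normalize_pair_key <- function(key) {
  if (grepl(",", key, fixed = TRUE)) {
    sides <- trimws(strsplit(key, ",", fixed = TRUE)[[1]])
    if (length(sides) != 2) stop("pair key must have two sides: ", key)
    return(pair_type_key(sides[1], sides[2]))
  }
  if (grepl("|", key, fixed = TRUE)) {
    sides <- strsplit(key, "|", fixed = TRUE)[[1]]
    return(pair_type_key(sides[1], sides[2]))
  }
  stop("malformed pair key: ", key)
}
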