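# Frequency/potential file: tab-separated text. Line 1 is a '#' header
# recording the training parameters; then a column-header line and one row
# per (pair type, bin). The reference distribution is stored under the
# reserved pair key "__REF__". Numbers are printed with %.17g so a
# write -> read -> write cycle is bit-identical.

REF_KEY <- "__REF__"

fmt_g <- function(x) sprintf("%.17g", x)

#' Write a frequency table to a TSV potential file
#'
#' @param ft A `frequency_table` from [train_frequency_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(ft, path) {
  g <- ft$grid
  header <- sprintf(
    "# bin_width=%s cutoff=%s min_separation=%d selection=%s min_count=%d total_count=%d",
    fmt_g(g$bin_width), fmt_g(g$cutoff), ft$params$min_separation,
    ft$params$selection, ft$params$min_count, as.integer(ft$total_count))
  lo <- g$breaks[-(g$n_bins + 1L)]
  hi <- g$breaks[-1L]
  rows <- character(0)
  row_block <- function(first, second, freq, count) {
    sprintf("%s\t%s\t%s\t%s\t%s\t%d",
            first, second, fmt_g(lo), fmt_g(hi), fmt_g(freq), as.integer(count))
  }
  keys <- names(ft$per_pair)
  for (k in keys) {
    p <- ft$per_pair[[k]]
    sides <- strsplit(k, "|", fixed = TRUE)[[1]]
    rows <- c(rows, row_block(sides[1], sides[2], as.numeric(p$freq), p$count))
  }
  rows <- c(rows, row_block(REF_KEY, REF_KEY, ft$reference, ft$total_count))
  writeLines(c(header,
               "pair_first\tpair_second\tbin_lo\tbin_hi\tf_obs\tcount",
               rows), path)
  invisible(path)
}

parse_header_line <- function(line) {
  kv <- strsplit(sub("^#\\s*", "", line), "\\s+")[[1]]
  parts <- strsplit(kv, "=", fixed = TRUE)
  vals <- vapply(parts, `[`, character(1), 2)
  names(vals) <- vapply(parts, `[`, character(1), 1)
  vals
}

#' Read a frequency table from a TSV potential file
#'
#' @param path Path written by [write_frequency_table()].
#' @return A `frequency_table`.
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "#"))
    stop("not a frequency table file: ", path)
  hv <- parse_header_line(lines[1])
  grid <- bin_grid(bin_width = as.numeric(hv[["bin_width"]]),
                   cutoff = as.numeric(hv[["cutoff"]]))
  tab <- utils::read.delim(text = lines[-1], header = TRUE,
                           stringsAsFactors = FALSE)
  min_count <- as.integer(hv[["min_count"]])
  key <- ifelse(tab$pair_first == REF_KEY, REF_KEY,
                pair_type_key(tab$pair_first, tab$pair_second))
  ref_rows <- tab[key == REF_KEY, , drop = FALSE]
  if (nrow(ref_rows) != grid$n_bins) stop("malformed reference block")
  pair_tab <- tab[key != REF_KEY, , drop = FALSE]
  pair_key <- key[key != REF_KEY]
  per_pair <- lapply(split(seq_len(nrow(pair_tab)), pair_key), function(i) {
    block <- pair_tab[i, , drop = FALSE]
    block <- block[order(block$bin_lo), , drop = FALSE]
    cnt <- block$count[1]
    freq <- block$f_obs
    ins <- cnt < min_count
    if (ins) attr(freq, "insufficient") <- TRUE
    list(freq = freq, count = cnt, insufficient = ins)
  })
  per_pair <- per_pair[order(names(per_pair))]
  ref <- ref_rows$f_obs[order(ref_rows$bin_lo)]
  structure(list(
    grid = grid,
    per_pair = per_pair,
    reference = ref,
    total_count = as.integer(hv[["total_count"]]),
    params = list(selection = hv[["selection"]],
                  min_separation = as.integer(hv[["min_separation"]]),
                  min_count = min_count,
                  bandwidth_rule = "scott")
  ), class = "frequency_table")
}
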