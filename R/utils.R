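# Shared helpers: matrix <-> tibble conversion, label normalisation, rounding.

#' Convert a CpG-by-sample tibble to a numeric matrix
#'
#' Methylation tables in deltameth are tibbles whose first column (`cpg_id`)
#' holds unique CpG identifiers and whose remaining columns are samples.
#' This helper strips the identifier column into rownames.
#'
#' @param tbl A CpG-by-sample tibble with a `cpg_id` column.
#' @return A numeric matrix with CpG rownames and sample colnames.
#' @export
meth_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl))
  if (!"cpg_id" %in% names(tbl)) {
    abort("expected a `cpg_id` column in the methylation table")
  }
  ids <- as.character(tbl$cpg_id)
  m <- as.matrix(tbl[setdiff(names(tbl), "cpg_id")])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Convert a numeric CpG-by-sample matrix back to a tibble
#'
#' @param m A numeric matrix with CpG rownames.
#' @return A tibble with a leading `cpg_id` column.
#' @export
meth_tibble <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  dplyr::bind_cols(
    tibble::tibble(cpg_id = rownames(m)),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
}

# lower_snake_case normalisation applied to categorical labels at read time
normalize_label <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("[^[:alnum:]]+", "_", x)
  x <- gsub("_+", "_", x)
  x <- gsub("^_|_$", "", x)
  tolower(x)
}

# round half up (Table-1 style percentages); base round() is round-half-even
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# deterministic child seeds derived from a user seed; kept < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) * 7919L
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
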