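#' Normalize chromosome labels
#'
#' Strips `chr`/`Chr`/`CHR` and the Animal-QTLdb-style `Chr.` prefixes and
#' upper-cases sex-chromosome letters, so that candidate tables (bare `5`),
#' Ensembl GTF (`5` or `chr5`) and QTLdb GFF (`Chr.5`) agree on a common
#' label. Numeric labels keep their digits; `X`, `Y`, `MT` stay as strings.
#'
#' @param x character or numeric vector of chromosome labels.
#' @return character vector of normalized labels; empty/NA input becomes `NA`.
#' @examples
#' norm_chrom(c("Chr.5", "chr5", "5", "x", "Chr.X"))
#' @export
norm_chrom <- function(x) {
  x <- stringr::str_trim(as.character(x))
  x <- stringr::str_remove(x, stringr::regex("^chr\\.?", ignore_case = TRUE))
  x <- toupper(x)
  x[!nzchar(x)] <- NA_character_
  x
}

# log(sum(exp(lx))) without overflow/underflow; lx may contain -Inf
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

# plain tbl_df view of a possibly-subclassed result (drops custom class and
# attributes so dplyr masking behaves predictably)
strip_tbl <- function(x) {
  x <- as_tibble(x)
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

# shared column-presence check with a caller-friendly error
check_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s (has: %s)",
      what, paste(missing, collapse = ", "), paste(names(df), collapse = ", ")
    ))
  }
  invisible(df)
}
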