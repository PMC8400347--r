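#' Normalize free text for lexicon and term matching
#'
#' Lowercases, maps hyphens to spaces, strips remaining punctuation, and
#' collapses whitespace. Archived ingredient labels and foodcode
#' descriptions vary typographically ("Sugar-Free", "sugar free",
#' "SUGAR FREE"); matching is always done on this normalized form.
#'
#' @param x character vector.
#' @return character vector of normalized text.
#' @export
#' @examples
#' normalize_text("Sugar-Free  Kool-Aid,  (powdered)")
normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[-‐‑–—/]", " ", x)
  x <- gsub("[^a-z0-9 ]", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Whole-token term matching in normalized text
#'
#' A single-word term matches only as a whole token ("diet" does not fire on
#' "dietary"); a multiword term matches as a contiguous token phrase.
#' Hyphen/space variants are equivalent because both sides are normalized.
#'
#' @param text character vector of free text.
#' @param terms character vector of search terms.
#' @return logical vector, `TRUE` where any term matches.
#' @export
matches_terms <- function(text, terms) {
  norm <- paste0(" ", normalize_text(text), " ")
  hit <- rep(FALSE, length(norm))
  for (term in normalize_text(terms)) {
    if (!nzchar(term)) next
    hit <- hit | grepl(paste0(" ", term, " "), norm, fixed = TRUE)
  }
  hit
}

# Split a semicolon-delimited ingredient field into trimmed entries.
split_ingredients <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

# stop() with a sprintf-style message and no call in the condition
bc_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Require columns in a data.frame read from disk.
check_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    bc_stop("file '%s' is missing required column(s): %s",
            path, paste(missing, collapse = ", "))
  }
  invisible(df)
}
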