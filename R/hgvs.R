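# HGVS-lite protein notation: one-letter ("L1296M", "W179*"), three-letter
# ("p.Leu1296Met", "p.Trp179Ter"), with optional "p." prefix and optional
# parentheses. Normalized to one-letter form; an alt of "*" marks a
# nonsense (stop-gain) change. Full HGVS (dup/del/ins/fs) is out of scope.

ONE_RE <- "^([A-Z])(\\d+)([A-Z*])$"
THREE_RE <- "^([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2}|\\*)$"

parse_one_protein <- function(tok) {
  s <- trimws(tok)
  s <- sub("^p\\.", "", s)
  s <- sub("^\\((.*)\\)$", "\\1", s)
  m <- stringr::str_match(s, ONE_RE)
  if (!is.na(m[1, 1])) {
    ref <- m[1, 2]
    alt <- m[1, 4]
    if (!ref %in% AA_ALPHABET || !(alt %in% c(AA_ALPHABET, "*"))) {
      return(NULL)
    }
    return(list(ref = ref, pos = as.integer(m[1, 3]), alt = alt))
  }
  m <- stringr::str_match(s, THREE_RE)
  if (!is.na(m[1, 1])) {
    ref3 <- m[1, 2]
    alt3 <- m[1, 4]
    if (alt3 == "*") alt3 <- "Ter"
    if (!ref3 %in% names(AA_THREE) || !alt3 %in% names(AA_THREE)) {
      return(NULL)
    }
    ref <- unname(AA_THREE[ref3])
    alt <- unname(AA_THREE[alt3])
    if (ref == "*") {
      return(NULL)
    }
    return(list(ref = ref, pos = as.integer(m[1, 3]), alt = alt))
  }
  NULL
}

#' Parse HGVS-lite protein change notation
#'
#' Accepts one-letter (`"L1296M"`, `"W179*"`) and three-letter
#' (`"p.Leu1296Met"`, `"p.Trp179Ter"`) substitutions, normalizing to
#' one-letter form. A stop alt (`*`/`Ter`) marks a nonsense change; all
#' other substitutions are missense. Synonymous and non-substitution
#' notation is rejected.
#'
#' @param x Character vector of protein-change tokens.
#' @return A tibble with columns `input`, `ref_aa`, `position`, `alt_aa`,
#'   `kind` (`"missense"` or `"nonsense"`).
#' @examples
#' parse_protein_hgvs(c("p.Leu1296Met", "W179*"))
#' @export
parse_protein_hgvs <- function(x) {
  if (length(x) == 0) {
    stop_parse("no protein change supplied")
  }
  parsed <- lapply(x, function(tok) {
    if (is.na(tok) || !nzchar(trimws(tok))) {
      return(NULL)
    }
    parse_one_protein(tok)
  })
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad)) {
    stop_parse(paste0(
      "cannot parse protein change token(s): ",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  ref <- vapply(parsed, `[[`, "", "ref")
  alt <- vapply(parsed, `[[`, "", "alt")
  if (any(ref == alt)) {
    stop_parse(paste0(
      "synonymous change not supported: ",
      paste(unique(x[ref == alt]), collapse = ", ")
    ))
  }
  tibble(
    input = as.character(x),
    ref_aa = ref,
    position = vapply(parsed, `[[`, 1L, "pos"),
    alt_aa = alt,
    kind = ifelse(alt == "*", "nonsense", "missense")
  )
}
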