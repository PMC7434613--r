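# Paralog conservation: per-column modal-residue frequency and its z-score
# across usable columns ("parazscore"). Negative values mark columns less
# conserved than the family average, positive values more conserved, with
# the maximum at columns where every paralog carries the same residue.

#' Raw conservation of one alignment column
#'
#' The fraction of non-gap entries in the column that carry the modal
#' (most frequent) residue. Gaps are excluded from the count, not treated
#' as a 21st residue state.
#'
#' @param aln A [paralog_alignment()].
#' @param column 1-based alignment column.
#' @return A single number in `[0, 1]`; `NA` when the column is all gaps.
#' @export
column_conservation <- function(aln, column) {
  stopifnot(inherits(aln, "paralog_alignment"))
  nc <- attr(aln, "n_columns")
  column <- as.integer(column)
  if (length(column) != 1L || is.na(column) || column < 1L || column > nc) {
    stop_index(paste0("column must be a single index in 1..", nc))
  }
  res <- substring(aln$aligned, column, column)
  res <- res[res != "-"]
  if (length(res) == 0) {
    return(NA_real_)
  }
  max(table(res)) / length(res)
}

#' Per-column conservation profile with parazscore
#'
#' Computes, for every alignment column, the raw conservation (modal
#' non-gap residue frequency), the number of non-gap entries, a usability
#' flag (`n_nongap >= min_nongap`), and the parazscore: the z-score of raw
#' conservation across usable columns, using the population (n) standard
#' deviation. Unusable columns carry `NA` parazscores.
#'
#' @param aln A [paralog_alignment()].
#' @param min_nongap Minimum non-gap entries for a column to be scored
#'   (default 3).
#' @return A `conservation_profile` tibble with columns `column`, `raw`,
#'   `n_nongap`, `usable`, `parazscore`.
#' @examples
#' aln <- paralog_alignment(
#'   data.frame(gene_id = c("A", "B", "C"), aligned = c("ACD", "ACE", "AGF")),
#'   reference_gene = "A"
#' )
#' parazscore_profile(aln, min_nongap = 2)
#' @export
parazscore_profile <- function(aln, min_nongap = 3) {
  stopifnot(inherits(aln, "paralog_alignment"))
  nc <- attr(aln, "n_columns")
  mat <- do.call(rbind, strsplit(aln$aligned, "", fixed = TRUE))
  raw <- numeric(nc)
  n_nongap <- integer(nc)
  for (j in seq_len(nc)) {
    col <- mat[, j]
    col <- col[col != "-"]
    n_nongap[j] <- length(col)
    raw[j] <- if (length(col)) max(tabulate(factor(col, levels = AA_ALPHABET))) / length(col) else NA_real_
  }
  usable <- n_nongap >= min_nongap
  if (!any(usable)) {
    stop_profile("no usable columns (all below min_nongap)")
  }
  r <- raw[usable]
  mu <- mean(r)
  sigma <- sqrt(mean((r - mu)^2)) # population denominator
  if (sigma == 0) {
    stop_profile("zero variance in raw conservation across usable columns; parazscore undefined")
  }
  paraz <- rep(NA_real_, nc)
  paraz[usable] <- (r - mu) / sigma
  out <- tibble(
    column = seq_len(nc),
    raw = raw,
    n_nongap = n_nongap,
    usable = usable,
    parazscore = paraz
  )
  class(out) <- c("conservation_profile", class(out))
  attr(out, "min_nongap") <- min_nongap
  out
}

#' Write a conservation profile as TSV
#'
#' @param profile A [parazscore_profile()] result.
#' @param path Output path; missing scores are written as `.`.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- as.data.frame(profile)
  readr::write_tsv(df, path, na = ".")
  invisible(path)
}

#' Conservation score of variant positions
#'
#' Looks up the parazscore of the alignment column a residue maps to.
#' Positions whose column is unusable (too few non-gap entries) return
#' `NA`.
#'
#' @param profile A [parazscore_profile()] result.
#' @param map An [alignment_index_map()].
#' @param gene Gene symbol(s).
#' @param residue 1-based residue position(s), recycled against `gene`.
#' @return Numeric vector of parazscores.
#' @export
score_variant_position <- function(profile, map, gene, residue) {
  cols <- residue_to_column(map, gene, residue)
  profile$parazscore[match(cols, profile$column)]
}

#' @export
autoplot.conservation_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(
    dplyr::filter(df, .data$usable),
    ggplot2::aes(x = .data$column, y = .data$parazscore)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$raw), size = 1) +
    ggplot2::scale_colour_viridis_c(name = "raw\nconservation") +
    ggplot2::labs(
      x = "alignment column",
      y = "parazscore (z of modal-residue frequency)"
    ) +
    ggplot2::theme_minimal()
}
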