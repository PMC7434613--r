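# Enrichment statistics: Welch two-tailed t on conservation scores, the
# two-sided Fisher exact kernel (hypergeometric tail summation), and a
# seeded Monte-Carlo permutation null for paralog-position co-occurrence.
# The test logic is implemented here from first principles on top of base
# distribution functions; stats::t.test / stats::fisher.test serve only as
# independent cross-checks in the test suite.

new_enrichment_result <- function(test, statistic, p_value, ..., alpha = 0.05) {
  structure(
    c(list(test = test, statistic = statistic, p_value = p_value, alpha = alpha),
      list(...)),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> ", x$test, "\n", sep = "")
  cat(" statistic = ", format(x$statistic, digits = 4),
    ", p = ", format(x$p_value, digits = 4), "\n",
    sep = ""
  )
  if (!is.null(x$table)) {
    print(x$table)
  }
  if (!is.null(x$permutation)) {
    cat(
      " permutation: B = ", x$permutation$B, ", observed = ",
      x$permutation$observed, ", null >= observed: ", x$permutation$n_ge,
      ", seed = ", x$permutation$seed %||% NA, "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(
    test = x$test,
    statistic = x$statistic,
    p.value = x$p_value,
    df = x$df %||% NA_real_,
    estimate = x$estimate %||% NA_real_
  )
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    test = x$test,
    statistic = x$statistic,
    p.value = x$p_value,
    alpha = x$alpha,
    n = x$n %||% NA_integer_,
    significant = x$p_value < x$alpha
  )
}

#' @export
autoplot.enrichment_result <- function(object, ...) {
  if (!is.null(object$permutation)) {
    df <- tibble(null = object$permutation$null_draws)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
        ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
        ggplot2::geom_vline(
          xintercept = object$permutation$observed,
          colour = "firebrick", linewidth = 1
        ) +
        ggplot2::labs(
          x = "null statistic", y = "permutations",
          title = paste0(object$test, " (p = ", format(object$p_value, digits = 3), ")")
        ) +
        ggplot2::theme_minimal()
    )
  }
  if (!is.null(object$table)) {
    df <- as.data.frame(as.table(object$table))
    names(df) <- c("row", "col", "n")
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
        ggplot2::geom_tile(ggplot2::aes(fill = .data$n), colour = "white") +
        ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
        ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
        ggplot2::labs(
          title = paste0(object$test, " (p = ", format(object$p_value, digits = 3), ")")
        ) +
        ggplot2::theme_minimal()
    )
  }
  df <- tibble(
    group = c(rep("case", length(object$case_scores)),
              rep("control", length(object$control_scores))),
    score = c(object$case_scores, object$control_scores)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      y = "parazscore",
      title = paste0(object$test, " (p = ", format(object$p_value, digits = 3), ")")
    ) +
    ggplot2::theme_minimal()
}

## ---- Welch t ---------------------------------------------------------------

welch_stats <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  v1 <- stats::var(x)
  v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Welch unequal-variance two-tailed t-test
#'
#' The unpaired t-test without the equal-variance assumption
#' (Welch–Satterthwaite degrees of freedom), appropriate when group sizes
#' are very different, as with a variant cohort against a population-scale
#' control set.
#'
#' @param x,y Numeric score vectors (each of length >= 2 with nonzero
#'   variance).
#' @param case_label,control_label Names used in error messages.
#' @return An `enrichment_result` with `statistic` (t), `df`, `p_value`.
#' @export
welch_ttest <- function(x, y, case_label = "x", control_label = "y") {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  for (g in list(list(v = x, lab = case_label), list(v = y, lab = control_label))) {
    if (length(g$v) < 2) {
      stop_stats(paste0("group '", g$lab, "' has fewer than 2 scores"))
    }
    if (stats::var(g$v) == 0) {
      stop_stats(paste0("group '", g$lab, "' has zero variance"))
    }
  }
  w <- welch_stats(x, y)
  new_enrichment_result(
    "welch_t", statistic = w$t, p_value = w$p, df = w$df,
    estimate = mean(x) - mean(y), n = length(x) + length(y),
    case_scores = x, control_scores = y
  )
}

#' Case-versus-control t-test on conservation scores
#'
#' Compares the parazscores of case variants against control (population)
#' variants with a two-tailed Welch t-test, asking whether case variants
#' sit at more conserved family positions than population variants do.
#'
#' @param data Annotated variant tibble with a score column and a cohort
#'   column.
#' @param score,cohort Column names (unquoted) holding the conservation
#'   score and the cohort label.
#' @param case_level,control_level Values of the cohort column defining
#'   the two groups.
#' @return An `enrichment_result`; see [welch_ttest()].
#' @export
parazscore_ttest <- function(data, score = parazscore, cohort = cohort,
                             case_level = "case", control_level = "control") {
  data <- as_tibble(data)
  sc <- rlang::eval_tidy(rlang::enquo(score), data)
  ch <- rlang::eval_tidy(rlang::enquo(cohort), data)
  out <- welch_ttest(
    sc[ch == case_level], sc[ch == control_level],
    case_label = case_level, control_label = control_level
  )
  out$test <- "parazscore_welch_t"
  out
}

## ---- Fisher exact ----------------------------------------------------------

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Computes the exact two-sided p-value by summing, over the
#' hypergeometric support implied by the fixed margins, the probabilities
#' of all tables no more probable than the observed one (with the
#' customary one-part-in-1e7 tie tolerance). A table with a zero margin is
#' uninformative and returns p = 1 with a warning.
#'
#' @param tab A 2x2 integer matrix, or the count `a` when `b`, `cc`, `d`
#'   are given.
#' @param b,cc,d Optional remaining cells (row-wise: `a` `b` / `cc` `d`).
#' @return An `enrichment_result` with the table, sample odds ratio and
#'   p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE))$p_value # 1/3
#' @export
fisher_exact_2x2 <- function(tab, b = NULL, cc = NULL, d = NULL) {
  if (!is.matrix(tab)) {
    tab <- matrix(c(tab, b, cc, d), 2, 2, byrow = TRUE)
  }
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    stop_value("fisher_exact_2x2() needs a 2x2 table of non-negative counts")
  }
  a <- tab[1, 1]
  m <- sum(tab[1, ]) # margin: row 1 total
  n <- sum(tab[2, ])
  k <- sum(tab[, 1]) # margin: column 1 total
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (m == 0 || n == 0 || k == 0 || sum(tab[, 2]) == 0) {
    rlang::warn("fisher_exact_2x2(): zero margin; p = 1")
    return(new_enrichment_result("fisher_exact", statistic = or,
      p_value = 1, table = tab, n = sum(tab)))
  }
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  new_enrichment_result("fisher_exact", statistic = or, p_value = p,
    table = tab, estimate = or, n = sum(tab))
}

derive_pathogenic <- function(data, quo) {
  if (!rlang::quo_is_null(quo)) {
    return(as.logical(rlang::eval_tidy(quo, data)))
  }
  if ("pathogenic" %in% names(data)) {
    return(as.logical(data$pathogenic))
  }
  if ("acmg_class" %in% names(data)) {
    return(data$acmg_class %in% c("P", "LP"))
  }
  if ("insilico" %in% names(data)) {
    return(data$insilico == "damaging")
  }
  stop_schema(
    "cannot derive a pathogenic label: supply `pathogenic` or provide an acmg_class/insilico column"
  )
}

#' Fisher test: pathogenic variants at conserved positions
#'
#' Builds the 2x2 table {pathogenic?, parazscore above the conserved cut?}
#' over variants with a conservation score and applies the two-sided
#' Fisher exact test. The conserved cut defaults to 0, i.e. above the
#' family-average conservation.
#'
#' @param data Annotated, classified variant tibble.
#' @param pathogenic Optional unquoted logical expression; by default a
#'   `pathogenic` column, else `acmg_class %in% c("P","LP")`, else
#'   `insilico == "damaging"`.
#' @param conserved_cut Parazscore threshold defining "conserved".
#' @return An `enrichment_result`.
#' @export
fisher_conserved <- function(data, pathogenic = NULL, conserved_cut = 0) {
  data <- as_tibble(data)
  lab <- derive_pathogenic(data, rlang::enquo(pathogenic))
  keep <- !is.na(data$parazscore) & !is.na(lab)
  lab <- lab[keep]
  cons <- data$parazscore[keep] > conserved_cut
  tab <- matrix(
    c(sum(lab & cons), sum(lab & !cons), sum(!lab & cons), sum(!lab & !cons)),
    2, 2, byrow = TRUE,
    dimnames = list(c("pathogenic", "not"), c("conserved", "not"))
  )
  out <- fisher_exact_2x2(tab)
  out$test <- "fisher_conserved"
  out$conserved_cut <- conserved_cut
  out
}

#' Fisher test: pathogenic variants in transmembrane regions
#'
#' Builds the 2x2 table {pathogenic?, region == transmembrane?} over
#' variants with a known region (rows with region `"unknown"` are dropped)
#' and applies the two-sided Fisher exact test.
#'
#' @inheritParams fisher_conserved
#' @return An `enrichment_result`.
#' @export
fisher_transmembrane <- function(data, pathogenic = NULL) {
  data <- as_tibble(data)
  lab <- derive_pathogenic(data, rlang::enquo(pathogenic))
  keep <- !is.na(data$region) & data$region != "unknown" & !is.na(lab)
  lab <- lab[keep]
  tm <- data$region[keep] == "transmembrane"
  tab <- matrix(
    c(sum(lab & tm), sum(lab & !tm), sum(!lab & tm), sum(!lab & !tm)),
    2, 2, byrow = TRUE,
    dimnames = list(c("pathogenic", "not"), c("transmembrane", "extramembrane"))
  )
  out <- fisher_exact_2x2(tab)
  out$test <- "fisher_transmembrane"
  out
}

## ---- permutation co-positioning test --------------------------------------

count_cross_gene_pairs <- function(columns, genes) {
  n <- length(columns)
  if (n < 2) {
    return(0L)
  }
  cnt <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (columns[i] == columns[j] && genes[i] != genes[j]) cnt <- cnt + 1L
    }
  }
  cnt
}

#' Permutation test for paralog-position co-occurrence
#'
#' Tests whether case variants land on particular alignment columns more
#' often than expected from the population positional distribution. The
#' statistic is either the number of case variants whose column falls in a
#' supplied target set of disease-associated columns (`mode = "target"`)
#' or the number of cross-gene pairs of case variants sharing a column
#' (`mode = "pairs"`). The null redraws the case columns from the control
#' column pool B times — with replacement by default, so draws are
#' frequency-weighted by the pool's multiplicities — and the p-value is
#' the add-one estimator `(1 + #\{null >= observed\}) / (1 + B)`, which can
#' never be exactly zero.
#'
#' @param case_columns Annotated case-variant tibble (columns `column`,
#'   `gene`) or an integer vector of alignment columns.
#' @param pool Integer vector of control (population) columns to resample
#'   from; multiplicities weight the null.
#' @param target_positions Integer set of target columns (required for
#'   `mode = "target"`).
#' @param mode `"target"` or `"pairs"`.
#' @param genes Gene labels parallel to the case columns (required for
#'   `mode = "pairs"` when `case_columns` is a bare vector).
#' @param B Number of permutations (>= 99; default 9999).
#' @param seed Integer seed making the run reproducible; `NULL` uses the
#'   current RNG state.
#' @param replace Resample with replacement (default). Without
#'   replacement, the pool must be at least as large as the case set.
#' @return An `enrichment_result` with a `permutation` provenance record
#'   (B, observed, count of null draws >= observed, seed, null draws).
#' @export
copositioning_test <- function(case_columns, pool, target_positions = NULL,
                               mode = c("target", "pairs"), genes = NULL,
                               B = 9999, seed = NULL, replace = TRUE) {
  mode <- match.arg(mode)
  if (is.data.frame(case_columns)) {
    df <- dplyr::filter(as_tibble(case_columns), !is.na(.data$column))
    genes <- df$gene
    case_columns <- df$column
  }
  if (length(case_columns) == 0) stop_stats("no case columns to test")
  if (B < 99) stop_value("B must be at least 99")
  if (!replace && length(pool) < length(case_columns)) {
    stop_sampling("pool smaller than the case set under without-replacement sampling")
  }
  if (mode == "target") {
    if (is.null(target_positions)) {
      stop_value("mode = 'target' needs a target_positions set (it is never fabricated)")
    }
    stat_fun <- function(cols) sum(cols %in% target_positions)
  } else {
    if (is.null(genes) || length(genes) != length(case_columns)) {
      stop_value("mode = 'pairs' needs gene labels parallel to the case columns")
    }
    stat_fun <- function(cols) count_cross_gene_pairs(cols, genes)
  }
  observed <- stat_fun(case_columns)
  draw_null <- function() {
    null_draws <- numeric(B)
    for (b in seq_len(B)) {
      null_draws[b] <- stat_fun(sample(pool, length(case_columns), replace = replace))
    }
    null_draws
  }
  null_draws <- if (is.null(seed)) draw_null() else withr::with_seed(seed, draw_null())
  n_ge <- sum(null_draws >= observed)
  p <- (1 + n_ge) / (1 + B)
  new_enrichment_result(
    paste0("copositioning_", mode),
    statistic = observed, p_value = p, n = length(case_columns),
    permutation = list(
      B = B, observed = observed, n_ge = n_ge, seed = seed,
      null_draws = null_draws
    )
  )
}
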