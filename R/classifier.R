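# Classification: six-tool in-silico consensus, splice-likelihood rule,
# and an "ACMG-lite" evidence engine with a fixed, documented combining
# table. The engine fires a small set of evidence codes (modelled on the
# ACMG code families) and maps the fired set to P/LP/VUS/LB/B; it is a
# deliberate simplification, not a 28-criterion ACMG implementation.

#' Default prediction-tool configuration
#'
#' Per-tool score ranges, orientation and damaging thresholds for the
#' six-tool panel (SIFT, PolyPhen-2 HVAR, PolyPhen-2 HDIV, Mutation
#' Assessor, FATHMM, LRT). Orientation `"low"` means small scores are
#' damaging (SIFT <= 0.05, FATHMM <= -1.5, LRT <= 0.001); `"high"` means
#' large scores are (PolyPhen-2 >= 0.5, Mutation Assessor >= 1.9).
#' Thresholds are configuration, not published values: the source studies
#' print scores without thresholds, so these defaults follow each tool's
#' common usage.
#'
#' @return A tibble with columns `tool`, `orientation`, `threshold`,
#'   `lower`, `upper`.
#' @export
prediction_tools <- function() {
  tibble(
    tool = c("sift", "polyphen2_hvar", "polyphen2_hdiv",
             "mutation_assessor", "fathmm", "lrt"),
    orientation = c("low", "high", "high", "high", "low", "low"),
    threshold = c(0.05, 0.5, 0.5, 1.9, -1.5, 0.001),
    lower = c(0, 0, 0, -6, -20, 0),
    upper = c(1, 1, 1, 6, 20, 1)
  )
}

consensus_verdict <- function(n_damaging, n_available) {
  dplyr::case_when(
    n_available < 4 ~ "insufficient",
    n_damaging >= 4 ~ "damaging",
    n_damaging <= 2 ~ "benign",
    TRUE ~ "conflicting"
  )
}

#' In-silico consensus over the prediction-tool panel
#'
#' Applies the majority rule over up to six pathogenicity predictors: a
#' variant is called `"damaging"` when at least 4 of the 6 tools predict a
#' functional effect, `"benign"` when at most 2 do (with at least 4 tools
#' available), `"conflicting"` otherwise, and `"insufficient"` when fewer
#' than 4 tools have scores. Calling 3-of-6 `"conflicting"` is this
#' implementation's reading of the boundary below the >= 4 rule.
#'
#' @param data Variant tibble with (a subset of) the tool score columns of
#'   [prediction_tools()].
#' @param tools Tool configuration tibble (see [prediction_tools()]).
#' @return `data` with `n_available`, `n_damaging` and `insilico` columns.
#' @export
insilico_consensus <- function(data, tools = prediction_tools()) {
  data <- as_tibble(data)
  present <- intersect(tools$tool, names(data))
  n <- nrow(data)
  avail <- matrix(FALSE, n, length(present))
  dmg <- matrix(FALSE, n, length(present))
  for (k in seq_along(present)) {
    cfg <- tools[tools$tool == present[k], ]
    x <- data[[present[k]]]
    out_of_range <- !is.na(x) & (x < cfg$lower | x > cfg$upper)
    if (any(out_of_range)) {
      stop_value(paste0(
        present[k], " score outside its documented range [", cfg$lower, ", ",
        cfg$upper, "] at row(s) ",
        paste(which(out_of_range), collapse = ", ")
      ))
    }
    avail[, k] <- !is.na(x)
    dmg[, k] <- !is.na(x) & (
      if (cfg$orientation == "low") x <= cfg$threshold else x >= cfg$threshold
    )
  }
  data$n_available <- as.integer(rowSums(avail))
  data$n_damaging <- as.integer(rowSums(dmg))
  data$insilico <- consensus_verdict(data$n_damaging, data$n_available)
  data
}

#' Classify splice-affecting likelihood
#'
#' A splice variant is in the damaging tier when its combined splice-tool
#' likelihood of affecting splicing is 50% or more (inclusive boundary).
#'
#' @param likelihood Numeric vector of percentages in `[0, 100]`.
#' @return Character vector `"damaging"`/`"not_damaging"` (`NA` passthrough).
#' @examples
#' splice_class(c(100, 50, 10))
#' @export
splice_class <- function(likelihood) {
  bad <- !is.na(likelihood) & (likelihood < 0 | likelihood > 100)
  if (any(bad)) {
    stop_value("splice likelihood must lie in [0, 100]")
  }
  ifelse(is.na(likelihood), NA_character_,
    ifelse(likelihood >= 50, "damaging", "not_damaging")
  )
}

ACMG_CLASS_LEVELS <- c("B", "LB", "VUS", "LP", "P")

# Combining table (fixed, documented):
#   pathogenic-strong  = nonsense (PVS1-like) or de novo (PS2-like)
#   pathogenic-moderate = AF below rarity threshold (PM2-like); rarity is
#     moderate, not strong, because reduced penetrance makes presence in
#     gnomAD compatible with pathogenicity
#   pathogenic-supporting = in-silico consensus damaging, or splice
#     likelihood >= 50% (PP3-like)
#   benign-strong = AF at or above the threshold (BS1-like)
#   benign-supporting = in-silico consensus benign (BP4-like)
# Rules, in order:
#   strong evidence in both directions        -> VUS (conflicting)
#   >= 2 pathogenic-strong                    -> P
#   1 pathogenic-strong (alone or with more)  -> LP
#   benign-strong, no pathogenic-strong       -> LB (B if also in-silico benign)
#   anything else (moderate/supporting mixes) -> VUS
classify_one <- function(kind, af, inheritance, insilico, splice_damaging,
                         rare_threshold, missing_af_is_zero) {
  ev <- character(0)
  if (identical(kind, "nonsense")) ev <- c(ev, "PVS1_like")
  if (identical(inheritance, "de_novo")) ev <- c(ev, "PS2_like")
  af_eff <- if (is.na(af) && missing_af_is_zero) 0 else af
  if (!is.na(af_eff)) {
    if (af_eff < rare_threshold) ev <- c(ev, "PM2_like") else ev <- c(ev, "BS1_like")
  }
  if (identical(insilico, "damaging") || isTRUE(splice_damaging)) ev <- c(ev, "PP3_like")
  if (identical(insilico, "benign")) ev <- c(ev, "BP4_like")

  n_strong_p <- sum(ev %in% c("PVS1_like", "PS2_like"))
  strong_b <- "BS1_like" %in% ev
  moderate_p <- "PM2_like" %in% ev
  supporting_p <- "PP3_like" %in% ev
  supporting_b <- "BP4_like" %in% ev

  conflicting <- (identical(insilico, "conflicting")) ||
    ((n_strong_p > 0 || moderate_p || supporting_p) && (strong_b || supporting_b))

  cls <- if (n_strong_p >= 1 && strong_b) {
    "VUS"
  } else if (n_strong_p >= 2) {
    "P"
  } else if (n_strong_p == 1) {
    "LP"
  } else if (strong_b) {
    if (supporting_b) "B" else "LB"
  } else {
    "VUS"
  }
  rationale <- paste0(
    "evidence: ", if (length(ev)) paste(ev, collapse = "+") else "none",
    " -> ", cls, if (conflicting) " (conflicting)" else ""
  )
  list(class = cls, evidence = ev, conflicting = conflicting, rationale = rationale)
}

#' ACMG-lite classification of variants
#'
#' Fires a documented subset of evidence codes per variant — nonsense
#' (PVS1-like, strong), de novo inheritance (PS2-like, strong), allele
#' frequency below the rarity threshold (PM2-like, moderate; rarity is
#' deliberately only moderate because the channel genes show reduced
#' penetrance), in-silico consensus damaging or splice likelihood >= 50%
#' (PP3-like, supporting), allele frequency at or above the threshold
#' (BS1-like, strong benign), in-silico consensus benign (BP4-like,
#' supporting benign) — and combines them with a fixed table:
#' strong evidence in both directions gives VUS flagged conflicting;
#' two or more pathogenic-strong gives P; one pathogenic-strong gives LP;
#' benign-strong without pathogenic-strong gives LB (B when the in-silico
#' consensus is also benign); every other combination is VUS. Every input
#' receives exactly one class.
#'
#' @param data Variant tibble; tool columns are consumed via
#'   [insilico_consensus()] if not already summarized.
#' @param rare_threshold Rarity threshold on gnomAD allele frequency
#'   (default 0.001). An AF of exactly 0 (absent from gnomAD) passes.
#' @param tools Tool configuration for [insilico_consensus()].
#' @param missing_af_is_zero Treat a missing AF as 0 (default) rather than
#'   as unknown.
#' @return `data` with `insilico`, `splice_verdict`, `acmg_class`,
#'   `evidence` (list-column of fired codes), `conflicting` and
#'   `rationale` columns.
#' @export
classify_variants <- function(data, rare_threshold = 0.001,
                              tools = prediction_tools(),
                              missing_af_is_zero = TRUE) {
  data <- as_tibble(data)
  if (nrow(data) == 0) {
    return(dplyr::mutate(data,
      insilico = character(), splice_verdict = character(),
      acmg_class = character(), evidence = list(),
      conflicting = logical(), rationale = character()
    ))
  }
  if (!"insilico" %in% names(data)) {
    data <- insilico_consensus(data, tools = tools)
  }
  data$splice_verdict <- splice_class(
    if ("splice_likelihood" %in% names(data)) data$splice_likelihood else rep(NA_real_, nrow(data))
  )
  res <- purrr::pmap(
    list(
      kind = if ("kind" %in% names(data)) data$kind else rep(NA_character_, nrow(data)),
      af = if ("af" %in% names(data)) data$af else rep(NA_real_, nrow(data)),
      inheritance = if ("inheritance" %in% names(data)) data$inheritance else rep("unknown", nrow(data)),
      insilico = data$insilico,
      splice_damaging = identical_chr(data$splice_verdict, "damaging")
    ),
    classify_one,
    rare_threshold = rare_threshold,
    missing_af_is_zero = missing_af_is_zero
  )
  data$acmg_class <- vapply(res, `[[`, "", "class")
  data$evidence <- lapply(res, `[[`, "evidence")
  data$conflicting <- vapply(res, `[[`, TRUE, "conflicting")
  data$rationale <- vapply(res, `[[`, "", "rationale")
  data
}

identical_chr <- function(x, value) !is.na(x) & x == value

#' Re-evaluate a variant set against the rarity threshold
#'
#' Classifies the table, deduplicates to unique variants, and reports the
#' class distribution, the variant- and carrier-level counts at or above
#' the allele-frequency threshold, and per-variant before/after labels
#' when an `original_class` column records previously published
#' assessments.
#'
#' @param data Variant tibble.
#' @param rare_threshold Frequency threshold (default 0.001).
#' @param ... Passed on to [classify_variants()].
#' @return A `reevaluation_report` list with elements `variants` (unique,
#'   classified), `by_class`, `af_filter` (one-row tibble), and
#'   `before_after` (tibble or `NULL`).
#' @export
reevaluate_variants <- function(data, rare_threshold = 0.001, ...) {
  data <- as_tibble(data)
  empty <- nrow(data) == 0
  classified <- classify_variants(data, rare_threshold = rare_threshold, ...)
  uniq <- deduplicate_variants(classified)
  by_class <- if (empty) {
    tibble(acmg_class = character(), n_variants = integer(), n_carriers = integer())
  } else {
    uniq |>
      dplyr::group_by(acmg_class = .data$acmg_class) |>
      dplyr::summarise(
        n_variants = dplyr::n(),
        n_carriers = sum(.data$n_carriers),
        .groups = "drop"
      )
  }
  af_eff <- ifelse(is.na(uniq$af), 0, uniq$af)
  over <- af_eff >= rare_threshold
  af_filter <- tibble(
    threshold = rare_threshold,
    n_variants_ge = sum(over),
    n_variants = nrow(uniq),
    n_carriers_ge = sum(uniq$n_carriers[over]),
    n_carriers = sum(uniq$n_carriers)
  )
  before_after <- NULL
  if ("original_class" %in% names(uniq) && !empty) {
    before_after <- tibble(
      gene = uniq$gene, cdna = uniq$cdna, protein = uniq$protein,
      before = uniq$original_class, after = uniq$acmg_class,
      changed = !is.na(uniq$original_class) & uniq$original_class != uniq$acmg_class
    )
  }
  structure(
    list(
      variants = uniq, by_class = by_class, af_filter = af_filter,
      before_after = before_after, rare_threshold = rare_threshold
    ),
    class = "reevaluation_report"
  )
}

#' @export
print.reevaluation_report <- function(x, ...) {
  cat("<reevaluation_report> ", nrow(x$variants), " unique variants, ",
    sum(x$variants$n_carriers), " carriers\n",
    sep = ""
  )
  print(x$by_class)
  cat(
    "AF >= ", x$rare_threshold, ": ", x$af_filter$n_variants_ge, "/",
    x$af_filter$n_variants, " variants, ", x$af_filter$n_carriers_ge, "/",
    x$af_filter$n_carriers, " carriers\n",
    sep = ""
  )
  invisible(x)
}

#' @export
glance.reevaluation_report <- function(x, ...) {
  tibble(
    n_variants = x$af_filter$n_variants,
    n_carriers = x$af_filter$n_carriers,
    n_variants_af_ge = x$af_filter$n_variants_ge,
    n_carriers_af_ge = x$af_filter$n_carriers_ge,
    threshold = x$rare_threshold,
    n_p_lp = sum(x$variants$acmg_class %in% c("P", "LP")),
    n_b_lb = sum(x$variants$acmg_class %in% c("B", "LB")),
    n_conflicting = sum(x$variants$conflicting)
  )
}
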