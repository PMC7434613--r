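# End-to-end pipeline stages with file IO and audit-ready reports. Each
# stage composes the module functions, embeds a run manifest (input paths
# and md5 hashes, config snapshot, seed, version, per-stage row counts)
# and is deterministic for fixed inputs and seed.

run_manifest <- function(inputs = character(), seed = NULL, counts = list(),
                         config = list()) {
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  input_tbl <- if (length(inputs)) {
    paths <- unlist(inputs)
    tibble(
      input = names(paths) %||% paths,
      path = unname(paths),
      md5 = unname(tools::md5sum(paths))
    )
  } else {
    tibble(input = character(), path = character(), md5 = character())
  }
  list(
    tool = "paravar",
    version = as.character(utils::packageVersion("paravar")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = input_tbl,
    config = config,
    counts = counts
  )
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(path)
}

as_alignment <- function(alignment, reference_gene = NULL) {
  if (inherits(alignment, "paralog_alignment")) {
    return(alignment)
  }
  read_alignment_fasta(alignment, reference_gene = reference_gene)
}

as_variants <- function(variants) {
  if (is.data.frame(variants)) {
    return(as_tibble(variants))
  }
  read_variant_table(variants)
}

as_domains <- function(domains) {
  if (is.null(domains)) {
    return(NULL)
  }
  if (is.data.frame(domains)) {
    return(as_tibble(domains))
  }
  read_domain_table(domains)
}

#' Annotate a variant table against a family alignment (pipeline stage)
#'
#' Composes alignment loading, conservation profiling and
#' [annotate_variants()]. With no domain architecture all regions are
#' `"unknown"` (with a warning). The result carries the run manifest in
#' attribute `"manifest"`.
#'
#' @param alignment A [paralog_alignment()] or aligned-FASTA path.
#' @param variants A variant tibble or TSV path.
#' @param domains Optional domain tibble or TSV path.
#' @param out Optional output TSV path.
#' @param reference_gene Anchor gene when reading FASTA.
#' @param skip_mismatch Report reference mismatches instead of erroring.
#' @param min_nongap Minimum non-gap entries per scored column.
#' @return Annotated variant tibble.
#' @export
run_annotate <- function(alignment, variants, domains = NULL, out = NULL,
                         reference_gene = NULL, skip_mismatch = FALSE,
                         min_nongap = 3) {
  aln <- as_alignment(alignment, reference_gene)
  var <- as_variants(variants)
  dom <- as_domains(domains)
  if (is.null(dom)) {
    rlang::warn("no domain architecture supplied; all regions set to 'unknown'")
  }
  profile <- parazscore_profile(aln, min_nongap = min_nongap)
  ann <- annotate_variants(var, aln, profile = profile, domains = dom,
                           skip_mismatch = skip_mismatch)
  attr(ann, "manifest") <- run_manifest(
    inputs = list(
      alignment = if (is.character(alignment)) alignment else NULL,
      variants = if (is.character(variants)) variants else NULL,
      domains = if (is.character(domains)) domains else NULL
    ),
    counts = list(
      n_sequences = nrow(aln), n_columns = n_columns(aln),
      n_variants = nrow(ann), n_mapped = sum(!is.na(ann$column))
    )
  )
  if (!is.null(out)) write_variant_tsv(ann, out)
  ann
}

#' Parse a key = value classifier configuration file
#'
#' Recognized keys: `rare_threshold` and `<tool>_threshold` for the six
#' panel tools (see [prediction_tools()]). Lines starting with `#` are
#' comments.
#'
#' @param file Path to the config file.
#' @return A list with elements `rare_threshold` and `tools`.
#' @export
read_classifier_config <- function(file) {
  if (!file.exists(file)) stop_schema(paste0("config file not found: ", file))
  lines <- readLines(file)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  tools <- prediction_tools()
  rare <- 0.001
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop_schema(paste0("config line not 'key = value': ", ln))
    key <- trimws(kv[1])
    val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (is.na(val)) stop_value(paste0("non-numeric config value for ", key))
    if (key == "rare_threshold") {
      rare <- val
    } else if (grepl("_threshold$", key)) {
      tool <- sub("_threshold$", "", key)
      if (!tool %in% tools$tool) stop_schema(paste0("unknown tool in config: ", tool))
      tools$threshold[tools$tool == tool] <- val
    } else {
      stop_schema(paste0("unknown config key: ", key))
    }
  }
  list(rare_threshold = rare, tools = tools)
}

#' Classify a variant table (pipeline stage)
#'
#' Runs the in-silico consensus, splice rule and ACMG-lite engine, and the
#' threshold re-evaluation report. Optionally writes a per-variant TSV and
#' a JSON report with the fired-evidence audit trail.
#'
#' @param variants Variant tibble or TSV path.
#' @param rare_threshold Rarity threshold (overridden by `config`).
#' @param config Optional [read_classifier_config()] path or list.
#' @param out Optional output TSV path (a `.json` report with the same
#'   stem is written alongside).
#' @return A `reevaluation_report` (see [reevaluate_variants()]).
#' @export
run_classify <- function(variants, rare_threshold = 0.001, config = NULL,
                         out = NULL) {
  var <- as_variants(variants)
  tools <- prediction_tools()
  if (!is.null(config)) {
    cfg <- if (is.character(config)) read_classifier_config(config) else config
    rare_threshold <- cfg$rare_threshold %||% rare_threshold
    tools <- cfg$tools %||% tools
  }
  report <- reevaluate_variants(var, rare_threshold = rare_threshold, tools = tools)
  manifest <- run_manifest(
    inputs = list(variants = if (is.character(variants)) variants else NULL),
    counts = list(
      n_rows = nrow(var), n_unique = nrow(report$variants),
      n_carriers = sum(report$variants$n_carriers)
    ),
    config = list(rare_threshold = rare_threshold)
  )
  report$manifest <- manifest
  if (!is.null(out)) {
    write_variant_tsv(report$variants, out)
    audit <- list(
      manifest = manifest,
      by_class = report$by_class,
      af_filter = report$af_filter,
      variants = dplyr::select(
        report$variants,
        dplyr::any_of(c("gene", "cdna", "protein", "af", "n_carriers",
                        "insilico", "acmg_class", "conflicting", "rationale")),
        "evidence"
      )
    )
    write_json_report(audit, sub("\\.tsv$", ".json", out))
  }
  report
}

strip_null <- function(x) x[!vapply(x, is.null, logical(1))]

#' Enrichment test battery (pipeline stage)
#'
#' Runs, where the inputs allow, the case-versus-control Welch t-test on
#' parazscores, the conserved-position and transmembrane Fisher tests, and
#' the seeded co-positioning permutation test (case columns against the
#' control column pool; `mode = "target"` additionally needs a known
#' disease-position set). Variants lacking a pathogenic label are labelled
#' via [classify_variants()] first.
#'
#' @param annotated Annotated variant tibble or TSV path (from
#'   [run_annotate()]).
#' @param B Permutation count.
#' @param seed Integer seed for the permutation null.
#' @param conserved_cut Parazscore cut defining "conserved".
#' @param mode Co-positioning statistic: `"pairs"` or `"target"`.
#' @param target_positions Optional integer vector of disease-associated
#'   columns (required for `mode = "target"`).
#' @param out Optional JSON report path.
#' @return Named list of `enrichment_result`s with a `manifest` element.
#' @export
run_enrich <- function(annotated, B = 9999, seed = NULL, conserved_cut = 0,
                       mode = c("pairs", "target"), target_positions = NULL,
                       out = NULL) {
  mode <- match.arg(mode)
  ann <- if (is.data.frame(annotated)) as_tibble(annotated) else read_variant_table(annotated)
  for (cc in c("column", "parazscore")) {
    if (cc %in% names(ann)) ann[[cc]] <- suppressWarnings(as.numeric(ann[[cc]]))
  }
  if (!"parazscore" %in% names(ann) || !"cohort" %in% names(ann)) {
    stop_schema("enrichment needs an annotated table with parazscore and cohort columns")
  }
  if (!any(c("pathogenic", "acmg_class", "insilico") %in% names(ann))) {
    ann <- classify_variants(ann)
  }
  # the clustering tests contrast variants called damaging by the
  # prediction-tool consensus against the rest (conflicting/benign)
  if (!"pathogenic" %in% names(ann) && "insilico" %in% names(ann)) {
    ann$pathogenic <- ann$insilico == "damaging"
  }
  results <- list()
  cases <- ann[ann$cohort == "case", , drop = FALSE]
  controls <- ann[ann$cohort == "control", , drop = FALSE]
  if (sum(!is.na(cases$parazscore)) >= 2 && sum(!is.na(controls$parazscore)) >= 2) {
    results$parazscore_ttest <- parazscore_ttest(ann)
  }
  results$fisher_conserved <- fisher_conserved(ann, conserved_cut = conserved_cut)
  if ("region" %in% names(ann) && any(ann$region != "unknown", na.rm = TRUE)) {
    results$fisher_transmembrane <- fisher_transmembrane(ann)
  }
  pool <- controls$column[!is.na(controls$column)]
  case_cols <- cases$column[!is.na(cases$column)]
  if (length(case_cols) >= 2 && length(pool) >= 1 &&
      (mode == "pairs" || !is.null(target_positions))) {
    results$copositioning <- copositioning_test(
      case_cols, pool,
      target_positions = target_positions, mode = mode,
      genes = cases$gene[!is.na(cases$column)], B = B, seed = seed
    )
  }
  manifest <- run_manifest(
    inputs = list(annotated = if (is.character(annotated)) annotated else NULL),
    seed = seed,
    counts = list(n_case = nrow(cases), n_control = nrow(controls)),
    config = list(B = B, conserved_cut = conserved_cut, mode = mode)
  )
  if (!is.null(out)) {
    payload <- lapply(results, function(r) {
      strip_null(list(
        test = r$test, statistic = r$statistic, p_value = r$p_value,
        df = r$df, table = if (!is.null(r$table)) as.vector(r$table),
        permutation = if (!is.null(r$permutation)) {
          r$permutation[c("B", "observed", "n_ge", "seed")]
        }
      ))
    })
    write_json_report(list(manifest = manifest, tests = payload), out)
  }
  results$manifest <- manifest
  results
}

#' Generate a synthetic fixture bundle (pipeline stage)
#'
#' Simulates a family, its variants and a domain architecture under one
#' seed and writes `family.fasta`, `variants.tsv`, `domains.tsv`,
#' `conserved_columns.tsv` and `manifest.json` to `outdir`.
#'
#' @param cfg A [sim_config()]; or pass `seed` (and `...` overrides) to
#'   build one.
#' @param outdir Output directory.
#' @param seed Seed used when `cfg` is missing.
#' @param ... Further [sim_config()] overrides.
#' @return `outdir`, invisibly.
#' @export
run_simulate <- function(outdir, cfg = NULL, seed = NULL, ...) {
  cfg <- cfg %||% sim_config(seed = seed, ...)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fam <- simulate_family(cfg)
  var <- simulate_variants(cfg, fam)
  dom <- simulate_domains(fam)
  write_alignment_fasta(fam$alignment, file.path(outdir, "family.fasta"))
  write_variant_tsv(var, file.path(outdir, "variants.tsv"))
  readr::write_tsv(dom, file.path(outdir, "domains.tsv"), na = ".")
  readr::write_tsv(
    tibble(column = fam$conserved_columns),
    file.path(outdir, "conserved_columns.tsv")
  )
  write_json_report(
    run_manifest(
      seed = cfg$seed,
      counts = list(
        n_sequences = nrow(fam$alignment),
        n_columns = n_columns(fam$alignment),
        n_conserved = length(fam$conserved_columns),
        n_case = cfg$n_case, n_control = cfg$n_control
      ),
      config = unclass(cfg)
    ),
    file.path(outdir, "manifest.json")
  )
  invisible(outdir)
}

#' End-to-end analysis report (pipeline stage)
#'
#' Annotate, classify and test in one call, writing the annotated TSV, the
#' classification TSV/JSON and the enrichment JSON under `outdir`.
#'
#' @inheritParams run_annotate
#' @inheritParams run_enrich
#' @param outdir Output directory.
#' @param rare_threshold Rarity threshold for classification.
#' @return A list with `annotated`, `classification`, `enrichment`.
#' @export
run_report <- function(alignment, variants, domains = NULL, outdir,
                       rare_threshold = 0.001, B = 9999, seed = NULL,
                       conserved_cut = 0, mode = "pairs",
                       target_positions = NULL, skip_mismatch = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- run_annotate(alignment, variants, domains,
    out = file.path(outdir, "annotated.tsv"), skip_mismatch = skip_mismatch
  )
  cls <- run_classify(ann, rare_threshold = rare_threshold,
    out = file.path(outdir, "classified.tsv")
  )
  labelled <- classify_variants(ann, rare_threshold = rare_threshold)
  enr <- run_enrich(labelled, B = B, seed = seed, conserved_cut = conserved_cut,
    mode = mode, target_positions = target_positions,
    out = file.path(outdir, "enrichment.json")
  )
  list(annotated = ann, classification = cls, enrichment = enr)
}
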