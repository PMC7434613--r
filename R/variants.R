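# Variant tables: TSV ingestion, per-variant deduplication with carrier
# counts, annotation with alignment column / conservation / membrane
# region, and cross-paralog position matching.

REQUIRED_VARIANT_COLS <- c("gene", "cdna", "protein", "af", "cohort")
NUMERIC_VARIANT_COLS <- c(
  "af", "splice_likelihood", "sift", "polyphen2_hvar", "polyphen2_hdiv",
  "mutation_assessor", "fathmm", "lrt", "parazscore_published"
)

#' Read a variant table (TSV)
#'
#' The table is tab-separated with a header row and `.` for missing values;
#' lines starting with `#` are provenance comments. Required columns:
#' `gene`, `cdna`, `protein`, `af`, `cohort` (`case` or `control`).
#' Recognized optional columns include `case_id`, `transcript`,
#' `inheritance` (`de_novo`/`inherited`/`unknown`), `zygosity`,
#' `splice_likelihood` (percent), the six prediction-tool scores (`sift`,
#' `polyphen2_hvar`, `polyphen2_hdiv`, `mutation_assessor`, `fathmm`,
#' `lrt`), and descriptive columns such as `age`, `hippocampus`,
#' `parazscore_published`, `acmg_published`, `original_class`, `notes`.
#'
#' Each row must carry exactly one of a protein change (parsed with
#' [parse_protein_hgvs()]) or a splice annotation (`splice_likelihood`
#' present with no protein change). A blank allele frequency is kept as
#' missing, which is distinct from an explicit `0` (absent from gnomAD).
#'
#' @param file Path to the TSV file.
#' @return A tibble of variant records with parsed `ref_aa`, `position`,
#'   `alt_aa`, `kind` columns and the source `row` number.
#' @export
read_variant_table <- function(file) {
  if (!file.exists(file)) stop_schema(paste0("variant table not found: ", file))
  df <- tryCatch(
    readr::read_tsv(
      file,
      col_types = readr::cols(.default = readr::col_character()),
      comment = "#", na = c(".", ""), progress = FALSE
    ),
    error = function(e) stop_schema(paste0("cannot read variant TSV: ", conditionMessage(e)))
  )
  parse_variant_frame(as_tibble(df))
}

# shared by the file reader and the synthetic generator (which builds the
# frame in memory)
parse_variant_frame <- function(df) {
  missing_cols <- setdiff(REQUIRED_VARIANT_COLS, names(df))
  if (nrow(df) == 0 || length(missing_cols)) {
    stop_schema(paste0(
      "variant table is empty or lacks required column(s): ",
      paste(if (length(missing_cols)) missing_cols else REQUIRED_VARIANT_COLS, collapse = ", ")
    ))
  }
  df$row <- seq_len(nrow(df))
  for (cc in intersect(NUMERIC_VARIANT_COLS, names(df))) {
    raw <- df[[cc]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & is.na(num)
    if (any(bad)) {
      stop_value(paste0(
        "non-numeric ", cc, " at row(s) ", paste(df$row[bad], collapse = ", ")
      ))
    }
    df[[cc]] <- num
  }
  bad_af <- !is.na(df$af) & (df$af < 0 | df$af > 1)
  if (any(bad_af)) {
    stop_value(paste0(
      "allele frequency outside [0, 1] at row(s) ",
      paste(df$row[bad_af], collapse = ", ")
    ))
  }
  if ("splice_likelihood" %in% names(df)) {
    bad_sp <- !is.na(df$splice_likelihood) &
      (df$splice_likelihood < 0 | df$splice_likelihood > 100)
    if (any(bad_sp)) {
      stop_value(paste0(
        "splice_likelihood outside [0, 100] at row(s) ",
        paste(df$row[bad_sp], collapse = ", ")
      ))
    }
  } else {
    df$splice_likelihood <- NA_real_
  }
  bad_cohort <- is.na(df$cohort) | !df$cohort %in% c("case", "control")
  if (any(bad_cohort)) {
    stop_value(paste0(
      "cohort must be 'case' or 'control'; offending row(s) ",
      paste(df$row[bad_cohort], collapse = ", ")
    ))
  }
  if (!"case_id" %in% names(df)) {
    df$case_id <- paste0("row", df$row)
  }
  if ("inheritance" %in% names(df)) {
    df$inheritance[is.na(df$inheritance)] <- "unknown"
    bad_inh <- !df$inheritance %in% c("de_novo", "inherited", "unknown")
    if (any(bad_inh)) {
      stop_value(paste0(
        "inheritance must be de_novo/inherited/unknown; offending row(s) ",
        paste(df$row[bad_inh], collapse = ", ")
      ))
    }
  } else {
    df$inheritance <- "unknown"
  }

  has_protein <- !is.na(df$protein)
  has_splice <- !is.na(df$splice_likelihood)
  neither <- !has_protein & !has_splice
  both <- has_protein & has_splice
  if (any(neither)) {
    stop_consistency(paste0(
      "row(s) with neither protein change nor splice annotation: ",
      paste(df$row[neither], collapse = ", ")
    ))
  }
  if (any(both)) {
    stop_consistency(paste0(
      "row(s) with both protein change and splice annotation: ",
      paste(df$row[both], collapse = ", ")
    ))
  }
  df$ref_aa <- NA_character_
  df$position <- NA_integer_
  df$alt_aa <- NA_character_
  df$kind <- ifelse(has_splice, "splice", NA_character_)
  if (any(has_protein)) {
    parsed <- tryCatch(
      parse_protein_hgvs(df$protein[has_protein]),
      paravar_parse_error = function(e) {
        stop_parse(paste0(
          conditionMessage(e), " (rows ",
          paste(df$row[has_protein], collapse = ", "), ")"
        ))
      }
    )
    df$protein[has_protein] <- paste0(parsed$ref_aa, parsed$position, parsed$alt_aa)
    df$ref_aa[has_protein] <- parsed$ref_aa
    df$position[has_protein] <- parsed$position
    df$alt_aa[has_protein] <- parsed$alt_aa
    df$kind[has_protein] <- parsed$kind
  }
  df
}

#' Write a variant table as TSV
#'
#' @param variants A variant tibble.
#' @param path Output path; missing values written as `.`.
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(variants, path) {
  out <- as.data.frame(variants)
  for (cc in names(out)) if (is.list(out[[cc]])) out[[cc]] <- vapply(out[[cc]], paste, "", collapse = ";")
  readr::write_tsv(out, path, na = ".")
  invisible(path)
}

#' Collapse variant rows to unique variants with carrier counts
#'
#' The unique-variant key is `(gene, cdna)`: distinct cDNA changes are kept
#' apart even when they predict the same protein change, matching
#' per-variant counting of recurrent alleles. Carrier count is the number
#' of distinct `case_id`s observed for the key; first-occurrence order is
#' preserved.
#'
#' @param records A variant tibble from [read_variant_table()].
#' @return One row per unique variant: the first occurrence's fields plus
#'   `n_carriers`, `carriers` (comma-joined ids) and `n_rows`.
#' @export
deduplicate_variants <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    return(dplyr::mutate(records, n_carriers = integer(), carriers = character(), n_rows = integer()))
  }
  key <- paste(records$gene, records$cdna, sep = "\r")
  prot_sig <- paste(records$ref_aa, records$position, records$alt_aa, records$kind)
  conflict <- tapply(prot_sig, key, function(v) length(unique(v)) > 1)
  if (any(conflict)) {
    bad <- names(conflict)[conflict]
    stop_consistency(paste0(
      "conflicting protein annotation for variant key(s): ",
      paste(gsub("\r", " ", bad), collapse = "; ")
    ))
  }
  first_idx <- !duplicated(key)
  carriers <- tapply(records$case_id, key, function(v) sort(unique(v)), simplify = FALSE)
  nrows <- tapply(seq_along(key), key, length)
  out <- records[first_idx, ]
  k <- key[first_idx]
  out$n_carriers <- unname(vapply(carriers[k], length, integer(1)))
  out$carriers <- unname(vapply(carriers[k], paste, "", collapse = ","))
  out$n_rows <- unname(as.integer(nrows[k]))
  out
}

#' Read a domain-architecture table (TSV)
#'
#' One row per transmembrane segment: columns `gene`, `domain` (e.g.
#' `DI`..`DIV`), `segment` (`S1`..`S6`), `start`, `end` (1-based residue
#' positions, inclusive on both ends). Ranges must not overlap within a
#' gene.
#'
#' @param file Path to the TSV.
#' @return A tibble of segment ranges.
#' @export
read_domain_table <- function(file) {
  if (!file.exists(file)) stop_schema(paste0("domain table not found: ", file))
  df <- readr::read_tsv(
    file,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", na = c(".", ""), progress = FALSE
  )
  need <- c("gene", "domain", "segment", "start", "end")
  if (!all(need %in% names(df))) {
    stop_schema(paste0(
      "domain table lacks required column(s): ",
      paste(setdiff(need, names(df)), collapse = ", ")
    ))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(is.na(df$start) | is.na(df$end) | df$start < 1 | df$end < df$start)) {
    stop_value("domain ranges must satisfy 1 <= start <= end")
  }
  overlap <- dplyr::group_by(df, .data$gene) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(bad = any(.data$start[-1] <= .data$end[-length(.data$end)]), .groups = "drop")
  if (any(overlap$bad)) {
    stop_consistency(paste0(
      "overlapping segment ranges within gene(s): ",
      paste(overlap$gene[overlap$bad], collapse = ", ")
    ))
  }
  as_tibble(df)
}

region_lookup <- function(gene, position, domains) {
  if (is.null(domains)) {
    return("unknown")
  }
  d <- domains[domains$gene == gene, , drop = FALSE]
  if (nrow(d) == 0) {
    return("unknown")
  }
  if (any(position >= d$start & position <= d$end)) "transmembrane" else "extramembrane"
}

#' Annotate variants with alignment column, conservation and region
#'
#' Missense variants in genes present in the alignment get their alignment
#' column, the column's parazscore and a membrane region from the domain
#' architecture. Splice and nonsense variants are not mappable onto the
#' alignment and keep a missing column with region `"unknown"`; missense
#' variants in genes absent from the alignment are annotated gracefully
#' absent (missing column). A missense reference residue that disagrees
#' with the aligned sequence raises a reference-mismatch error, or — with
#' `skip_mismatch = TRUE` — is reported in the `mismatch` column and left
#' unannotated.
#'
#' Re-annotating an already annotated table overwrites the derived columns,
#' so the operation is idempotent.
#'
#' @param variants A variant tibble from [read_variant_table()].
#' @param aln A [paralog_alignment()].
#' @param profile Optional precomputed [parazscore_profile()]; computed
#'   from `aln` when `NULL`.
#' @param domains Optional [read_domain_table()] tibble; when `NULL` all
#'   regions are `"unknown"`.
#' @param skip_mismatch Report reference mismatches instead of erroring.
#' @return The input with `column`, `parazscore`, `region` and `mismatch`
#'   columns added.
#' @export
annotate_variants <- function(variants, aln, profile = NULL, domains = NULL,
                              skip_mismatch = FALSE) {
  stopifnot(inherits(aln, "paralog_alignment"))
  variants <- as_tibble(variants)
  variants$column <- NULL
  variants$parazscore <- NULL
  variants$region <- NULL
  variants$mismatch <- NULL
  profile <- profile %||% parazscore_profile(aln)
  map <- alignment_index_map(aln)
  residues <- alignment_residues(aln)

  n <- nrow(variants)
  col_out <- rep(NA_integer_, n)
  paraz_out <- rep(NA_real_, n)
  region_out <- rep("unknown", n)
  mm_out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    if (!identical(v$kind, "missense")) next
    region_out[i] <- region_lookup(v$gene, v$position, domains)
    if (!v$gene %in% aln$gene_id) next
    seq_len_gene <- nchar(residues[[v$gene]])
    if (v$position > seq_len_gene) {
      msg <- paste0(
        "row ", v$row, ": residue ", v$position, " beyond length of ",
        v$gene, " (", seq_len_gene, ")"
      )
      if (skip_mismatch) {
        mm_out[i] <- msg
        next
      }
      stop_coordinate(msg)
    }
    found <- substring(residues[[v$gene]], v$position, v$position)
    if (found != v$ref_aa) {
      msg <- paste0(
        "row ", v$row, ": reference mismatch for ", v$gene, " ", v$protein,
        " (alignment has ", found, " at residue ", v$position, ")"
      )
      if (skip_mismatch) {
        mm_out[i] <- msg
        next
      }
      stop_mismatch(msg)
    }
    col_out[i] <- residue_to_column(map, v$gene, v$position)
    paraz_out[i] <- profile$parazscore[match(col_out[i], profile$column)]
  }
  variants$column <- col_out
  variants$parazscore <- paraz_out
  variants$region <- region_out
  variants$mismatch <- mm_out
  variants
}

#' Cross-paralog position matches among annotated variants
#'
#' Reports (a) every pair of variants from *different* genes whose missense
#' changes map to the same alignment column (pairs within one gene are
#' excluded), and (b), when a set of known disease-associated columns is
#' supplied, the variants landing on those columns. The disease-position
#' set is an optional external input and is never fabricated.
#'
#' @param annotated An [annotate_variants()] result.
#' @param known_disease_positions Optional integer vector of alignment
#'   columns reported in disease.
#' @return A `paralog_match_report` list with tibbles `pairs` and
#'   `at_known_positions`.
#' @export
find_paralog_matches <- function(annotated, known_disease_positions = NULL) {
  annotated <- as_tibble(annotated)
  mapped <- dplyr::filter(annotated, !is.na(.data$column))
  mapped$variant_id <- paste(mapped$gene, mapped$cdna, sep = ":")
  pairs <- tibble(
    column = integer(), gene1 = character(), variant1 = character(),
    gene2 = character(), variant2 = character()
  )
  if (nrow(mapped) >= 2) {
    idx <- split(seq_len(nrow(mapped)), mapped$column)
    for (rows in idx) {
      if (length(rows) < 2) next
      cmb <- utils::combn(rows, 2)
      for (k in seq_len(ncol(cmb))) {
        a <- cmb[1, k]
        b <- cmb[2, k]
        if (mapped$gene[a] == mapped$gene[b]) next
        pairs <- dplyr::bind_rows(pairs, tibble(
          column = mapped$column[a],
          gene1 = mapped$gene[a], variant1 = mapped$variant_id[a],
          gene2 = mapped$gene[b], variant2 = mapped$variant_id[b]
        ))
      }
    }
  }
  at_known <- if (is.null(known_disease_positions)) {
    tibble(column = integer(), gene = character(), variant_id = character())
  } else {
    hit <- mapped[mapped$column %in% known_disease_positions, , drop = FALSE]
    tibble(column = hit$column, gene = hit$gene, variant_id = hit$variant_id)
  }
  structure(
    list(pairs = pairs, at_known_positions = at_known,
         known_positions_supplied = !is.null(known_disease_positions)),
    class = "paralog_match_report"
  )
}

#' @export
print.paralog_match_report <- function(x, ...) {
  cat("<paralog_match_report>\n")
  cat(" cross-gene same-column pairs:", nrow(x$pairs), "\n")
  if (x$known_positions_supplied) {
    cat(" variants at known disease positions:", nrow(x$at_known_positions), "\n")
  } else {
    cat(" (no known disease-position set supplied)\n")
  }
  invisible(x)
}
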