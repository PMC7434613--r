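# Seeded synthetic data: paralog families with mixed-conservation columns,
# case/control variant sets with a tunable conserved-column enrichment,
# correlated prediction panels, and allele frequencies spanning the 0.001
# rarity threshold. Everything is deterministic under a fixed seed so the
# whole pipeline is testable without downloads.

#' Simulation configuration
#'
#' Defines the generative model: an ancestral protein of
#' `sequence_length` residues is copied into `n_paralogs` family members;
#' a fraction `fraction_conserved` of columns is designated conserved and
#' mutates at `rate_conserved` per copy, the rest at `rate_variable`
#' (uniform replacement over the 19 alternative residues — deliberately
#' non-biological, sufficient for conservation structure). Case variants
#' land on a conserved column with excess probability `enrichment_delta`
#' (0 = same positional distribution as controls); control variants are
#' uniform over columns. Prediction panels are correlated with
#' conservation through `panel_strength` (0 = pure noise, 1 = tool
#' damaging-call probability 0.9 on conserved vs 0.1 on variable columns).
#' Allele frequencies come from a three-component log-uniform mixture with
#' breakpoints `af_breaks` and weights `af_weights`, spanning both sides
#' of the 0.001 rarity threshold.
#'
#' The defaults mirror the analysis this package implements: 74 case
#' variants (a cohort-plus-literature sized missense set) against 1000
#' population control variants, nine paralogs, and a strong conserved-site
#' enrichment.
#'
#' @param n_paralogs,sequence_length Family size and protein length.
#' @param fraction_conserved Fraction of columns designated conserved.
#' @param rate_conserved,rate_variable Per-copy substitution rates.
#' @param gap_fraction Optional per-gene fraction of residues replaced by
#'   gaps (default 0: gap-free).
#' @param n_case,n_control Number of case / control variants.
#' @param enrichment_delta Excess probability that a case variant lands on
#'   a conserved column.
#' @param panel_strength Correlation of the prediction panel with
#'   conservation, in `[0, 1]`.
#' @param af_breaks,af_weights Allele-frequency mixture: log-uniform
#'   within consecutive `af_breaks` intervals, mixed with `af_weights`.
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_paralogs = 9, sequence_length = 200,
                       fraction_conserved = 0.3,
                       rate_conserved = 0.05, rate_variable = 0.5,
                       gap_fraction = 0,
                       n_case = 74, n_control = 1000,
                       enrichment_delta = 0.5, panel_strength = 0.8,
                       af_breaks = c(1e-6, 1e-4, 1e-3, 1e-2),
                       af_weights = c(0.7, 0.2, 0.1),
                       seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop_config("sim_config() requires an explicit integer seed")
  }
  if (sequence_length < 1) stop_config("sequence_length must be positive")
  if (n_paralogs < 2) stop_config("n_paralogs must be at least 2")
  fracs <- c(fraction_conserved, rate_conserved, rate_variable, gap_fraction,
             enrichment_delta, panel_strength)
  if (any(fracs < 0 | fracs > 1)) {
    stop_config("all fractions and rates must lie in [0, 1]")
  }
  if (length(af_weights) != length(af_breaks) - 1 || abs(sum(af_weights) - 1) > 1e-9) {
    stop_config("af_weights must sum to 1 with one weight per af_breaks interval")
  }
  structure(
    list(
      n_paralogs = as.integer(n_paralogs),
      sequence_length = as.integer(sequence_length),
      fraction_conserved = fraction_conserved,
      rate_conserved = rate_conserved,
      rate_variable = rate_variable,
      gap_fraction = gap_fraction,
      n_case = as.integer(n_case),
      n_control = as.integer(n_control),
      enrichment_delta = enrichment_delta,
      panel_strength = panel_strength,
      af_breaks = af_breaks,
      af_weights = af_weights,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

mutate_sequence <- function(chars, rate_per_pos) {
  hit <- runif(length(chars)) < rate_per_pos
  if (any(hit)) {
    chars[hit] <- vapply(
      chars[hit],
      function(a) sample(setdiff(AA_ALPHABET, a), 1),
      "", USE.NAMES = FALSE
    )
  }
  chars
}

#' Simulate a paralog family with planted conserved columns
#'
#' Draws a uniform ancestral sequence, designates
#' `round(fraction_conserved * sequence_length)` columns as conserved, and
#' mutates each paralog independently (low rate on conserved columns, high
#' rate elsewhere). Gap-free by default; with `gap_fraction > 0` a random
#' subset of residues per gene is replaced by gaps. Fully deterministic
#' under the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A list with `alignment` (a [paralog_alignment()]) and
#'   `conserved_columns` (the planted truth set, sorted).
#' @export
simulate_family <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    L <- cfg$sequence_length
    ancestral <- sample(AA_ALPHABET, L, replace = TRUE)
    n_cons <- round(cfg$fraction_conserved * L)
    conserved <- sort(sample.int(L, n_cons))
    rate <- rep(cfg$rate_variable, L)
    rate[conserved] <- cfg$rate_conserved
    rows <- lapply(seq_len(cfg$n_paralogs), function(g) {
      chars <- mutate_sequence(ancestral, rate)
      if (cfg$gap_fraction > 0) {
        gaps <- runif(L) < cfg$gap_fraction
        chars[gaps] <- "-"
      }
      paste(chars, collapse = "")
    })
    aln <- paralog_alignment(
      tibble(
        gene_id = sprintf("PARA%d", seq_len(cfg$n_paralogs)),
        transcript_id = sprintf("TX%d", seq_len(cfg$n_paralogs)),
        aligned = unlist(rows)
      ),
      reference_gene = "PARA1"
    )
    list(alignment = aln, conserved_columns = conserved)
  })
}

sample_af <- function(n, breaks, weights) {
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  lo <- log10(breaks[comp])
  hi <- log10(breaks[comp + 1])
  10^(lo + runif(n) * (hi - lo))
}

tool_score <- function(damaging, tool) {
  cfg <- prediction_tools()
  cfg <- cfg[cfg$tool == tool, ]
  n <- length(damaging)
  if (cfg$orientation == "low") {
    ifelse(damaging,
      runif(n, cfg$lower, cfg$threshold),
      runif(n, cfg$threshold + (cfg$upper - cfg$threshold) * 0.05, cfg$upper)
    )
  } else {
    ifelse(damaging,
      runif(n, cfg$threshold, cfg$upper),
      runif(n, cfg$lower, cfg$threshold - (cfg$threshold - cfg$lower) * 0.05)
    )
  }
}

#' Simulate case and control variant records
#'
#' Draws `n_control` control variants with positions uniform over columns
#' and `n_case` case variants whose positions land on a planted conserved
#' column with excess probability `enrichment_delta`; genes are uniform.
#' Reference residues are read off the simulated sequences, so every
#' synthesized missense record annotates without reference mismatches.
#' Prediction panels are sampled so the probability of a damaging call
#' rises with conservation, and allele frequencies follow the configured
#' mixture. Uses the stream `seed + 1` so the family and the variant set
#' are independently reproducible.
#'
#' @param cfg A [sim_config()].
#' @param family A [simulate_family()] result.
#' @return A variant tibble (cases and controls stacked, `cohort` column)
#'   in the same schema as [read_variant_table()].
#' @export
simulate_variants <- function(cfg, family) {
  stopifnot(inherits(cfg, "sim_config"))
  aln <- family$alignment
  conserved <- family$conserved_columns
  L <- n_columns(aln)
  if (cfg$n_case + cfg$n_control < 1) stop_config("no variants requested")
  map <- alignment_index_map(aln)
  chars <- strsplit(aln$aligned, "", fixed = TRUE)
  names(chars) <- aln$gene_id
  withr::with_seed(cfg$seed + 1L, {
    draw_one <- function(is_case) {
      for (try in 1:1000) {
        gene <- sample(aln$gene_id, 1)
        col <- if (is_case && length(conserved) > 0 && runif(1) < cfg$enrichment_delta) {
          conserved[sample.int(length(conserved), 1)]
        } else {
          sample.int(L, 1)
        }
        ref <- chars[[gene]][col]
        if (ref != "-") {
          return(list(gene = gene, column = col, ref = ref))
        }
      }
      stop_config("could not draw a non-gap position; alignment too gappy")
    }
    n_tot <- cfg$n_case + cfg$n_control
    is_case <- c(rep(TRUE, cfg$n_case), rep(FALSE, cfg$n_control))
    draws <- lapply(is_case, draw_one)
    gene <- vapply(draws, `[[`, "", "gene")
    col <- vapply(draws, `[[`, 1L, "column")
    ref <- vapply(draws, `[[`, "", "ref")
    pos <- column_to_residue(map, gene, col)
    alt <- vapply(ref, function(a) sample(setdiff(AA_ALPHABET, a), 1), "",
                  USE.NAMES = FALSE)
    on_conserved <- col %in% conserved
    p_dmg <- (1 - cfg$panel_strength) * 0.5 +
      cfg$panel_strength * ifelse(on_conserved, 0.9, 0.1)
    panel <- lapply(prediction_tools()$tool, function(tl) {
      tool_score(runif(n_tot) < p_dmg, tl)
    })
    names(panel) <- prediction_tools()$tool
    df <- tibble(
      gene = gene,
      transcript = paste0("TX_", gene),
      cdna = sprintf("%d%s>%s", 3L * pos - 2L, ref, alt),
      protein = paste0(ref, pos, alt),
      af = sample_af(n_tot, cfg$af_breaks, cfg$af_weights),
      cohort = ifelse(is_case, "case", "control"),
      case_id = ifelse(is_case,
        sprintf("CASE%04d", cumsum(is_case)),
        sprintf("CTRL%04d", cumsum(!is_case))
      ),
      inheritance = "unknown"
    )
    for (tl in names(panel)) df[[tl]] <- panel[[tl]]
    parse_variant_frame(df)
  })
}

#' Deterministic transmembrane architecture for a simulated family
#'
#' Tiles each gene with evenly spaced membrane-spanning segments covering
#' about `fraction_tm` of the sequence, labelled with cycling domain
#' (DI–DIV) and segment (S1–S6) names. Deterministic (no randomness), in
#' the same schema as [read_domain_table()].
#'
#' @param family A [simulate_family()] result (or a [paralog_alignment()]).
#' @param fraction_tm Fraction of each sequence inside segments.
#' @return A domain-architecture tibble.
#' @export
simulate_domains <- function(family, fraction_tm = 0.4) {
  aln <- if (inherits(family, "paralog_alignment")) family else family$alignment
  res <- alignment_residues(aln)
  out <- lapply(names(res), function(g) {
    L <- nchar(res[[g]])
    n_seg <- max(1L, min(24L, L %/% 25L))
    spacing <- L / n_seg
    tm_len <- max(1L, floor(spacing * fraction_tm))
    starts <- floor((seq_len(n_seg) - 1) * spacing) + 1L
    tibble(
      gene = g,
      domain = paste0("D", c("I", "II", "III", "IV")[((seq_len(n_seg) - 1) %/% 6) %% 4 + 1]),
      segment = paste0("S", (seq_len(n_seg) - 1) %% 6 + 1),
      start = starts,
      end = pmin(starts + tm_len - 1L, L)
    )
  })
  dplyr::bind_rows(out)
}

## ---- packaged fixtures ----------------------------------------------------

#' Cohort variant table (11 VGSC variants in 10 SUDP cases)
#'
#' Transcription of the curated cohort annotation distributed with this
#' package: 12 rows covering 11 unique voltage-gated sodium channel
#' variants in 10 sudden-unexpected-death-in-pediatrics cases (one case
#' carries two variants in cis; two siblings share one nonsense variant).
#' The `parazscore_published` and `acmg_published` columns carry the
#' original expert annotations as descriptive inputs; they are not
#' recomputed by this package (the underlying alignment/score resource is
#' unpublished).
#'
#' @return A variant tibble in the [read_variant_table()] schema.
#' @export
cohort_variants_table <- function() {
  df <- tibble(
    gene = c("SCN1A", "SCN1A", "SCN1A", "SCN1A", "SCN3A", "SCN4A", "SCN4A",
             "SCN9A", "SCN10A", "SCN10A", "SCN1B", "SCN1B"),
    case_id = c("Case1", "Case1", "Case2", "Case3", "Case4", "Case5", "Case6",
                "Case7", "Case4", "Case8", "Case9", "Case10"),
    transcript = c(rep("NM_001165963.1", 4), "NM_006922.3", "NM_000334.3",
                   "NM_000334.3", "NM_002977.3", "NM_006514.2", "NM_006514.2",
                   "NM_199037.4", "NM_199037.4"),
    cdna = c("3886T>A", "3924A>T", "2045G>T", "182T>C", "5411C>T", "2171A>G",
             "307T>G", "5624G>A", "4386+1G>C", "305C>G", "536G>A", "536G>A"),
    protein = c("L1296M", "E1308D", "G682V", "L61P", "A1804V", "K724R",
                "F103V", "R1875Q", NA, "S102C", "W179*", "W179*"),
    af = c(8.17e-6, 6.416e-4, 4.07e-6, 0, 2.44e-5, 0, 2.03e-5, 1.62e-5,
           1.22e-5, 4.07e-6, 8.19e-6, 8.19e-6),
    sift = c(0.001, 0.281, 0.003, 0, 0, 0.001, 0.001, 0, NA, 0.002, NA, NA),
    polyphen2_hvar = c(0.979, 0.727, 0.478, 0.783, 0.998, 0.953, 0.73, 0.734,
                       NA, 0.701, NA, NA),
    splice_likelihood = c(rep(NA, 8), 100, NA, NA, NA),
    parazscore_published = c(0.49, -1.23, -1.48, 1.23, -0.49, 0.25, -0.25, 0,
                             NA, -0.25, NA, NA),
    acmg_published = c("P", "LP", "LP", "LP", "VUS", "P", "VUS", "VUS", "VUS",
                       "VUS", "LP", "LP"),
    inheritance = c("unknown", "unknown", "unknown", "unknown", "unknown",
                    "inherited", "inherited", "inherited", "unknown",
                    "inherited", "unknown", "unknown"),
    zygosity = "het",
    age = c("7 weeks", "7 weeks", "2 months", "20 months", "4 months",
            "5 months", "3 months", "8 years", "4 months", "3 months 22 days",
            "4 months", "2 months"),
    hippocampus = c("abnormal", "abnormal", "abnormal", "abnormal", NA,
                    "normal", "abnormal", "abnormal", NA, "abnormal",
                    "abnormal", NA),
    notes = c("in cis with E1308D; abnormal dentate gyrus",
              "in cis with L1296M", "abnormal dentate gyrus",
              "end-folium sclerosis; atypical febrile seizures", NA,
              "megalencephaly; normal hippocampus",
              "megalencephaly; abnormal dentate gyrus",
              "Chiari malformation 1; abnormal dentate gyrus",
              "splice-site variant, same case as SCN3A A1804V",
              "megalencephaly; abnormal dentate gyrus",
              "sibling of Case10", "sibling of Case9"),
    cohort = "case"
  )
  parse_variant_frame(df)
}

# protein lengths used for the synthetic literature reconstruction
LIT_GENE_LENGTHS <- c(
  SCN1A = 2009, SCN4A = 1836, SCN5A = 2016, SCN10A = 1956,
  SCN1B = 268, SCN3B = 215, SCN4B = 228
)

#' Synthetic literature variant set (reconstruction)
#'
#' A synthetic stand-in for the merged literature review of sodium-channel
#' variants in sudden unexpected pediatric death: the underlying
#' per-variant supplementary table is not published alongside the study
#' text, so this fixture realizes its printed marginal counts exactly —
#' 82 unique variants carried by 103 individuals (109 carrier rows; six
#' individuals harbor two variants), per-gene counts SCN1A 3 / SCN4A 6 /
#' SCN5A 62 / SCN10A 4 / SCN1B 3 / SCN3B 3 / SCN4B 1, twelve recurrent
#' variants in 39 individuals topped by SCN5A R1193Q (8 carriers) and
#' L567Q (7), 14 variants (31 carriers) at allele frequency >= 0.001, 81
#' distinct amino-acid positions, and a 3-variant overlap with the cohort
#' table (the SCN1A trio), so the merged set has 90 unique variants.
#' Everything beyond these published marginals (exact positions, scores,
#' frequencies) is synthesized under a fixed seed and is NOT real data.
#'
#' @return A variant tibble in the [read_variant_table()] schema, with an
#'   `original_class` column of plausible historical labels.
#' @export
literature_variants_synthetic <- function() {
  withr::with_seed(424242L, {
    # unique variants: gene, position, ref, alt, cdna, n_carriers, common?
    overlap <- tibble(
      gene = "SCN1A",
      position = c(1296L, 1308L, 682L),
      ref = c("L", "E", "G"),
      alt = c("M", "D", "V"),
      cdna = c("3886T>A", "3924A>T", "2045G>T"),
      n_carriers = 1L
    )
    # SCN5A: 62 variants; R1193Q and L567Q plus 60 synthesized, one shared
    # position (two alts) so the 82 variants affect 81 distinct positions
    scn5a_pool <- setdiff(seq_len(LIT_GENE_LENGTHS[["SCN5A"]]), c(1193L, 567L))
    scn5a_pos <- sample(scn5a_pool, 59)
    pos5 <- c(1193L, 567L, scn5a_pos, scn5a_pos[1])
    ref5 <- c("R", "L", vapply(seq_len(59), function(i) sample(AA_ALPHABET, 1), ""))
    ref5 <- c(ref5, ref5[3]) # duplicated position keeps its reference
    alt5 <- c("Q", "Q", vapply(ref5[3:61], function(a) sample(setdiff(AA_ALPHABET, a), 1), ""))
    alt5 <- c(alt5, sample(setdiff(AA_ALPHABET, c(ref5[3], alt5[3])), 1))
    cdna5 <- c(
      "3578G>A", "1700T>A",
      sprintf("%dG>A", 3L * pos5[3:61] - 2L),
      sprintf("%dG>C", 3L * pos5[62] - 2L)
    )
    carriers5 <- c(8L, 7L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, rep(1L, 50))
    scn5a <- tibble(
      gene = "SCN5A", position = pos5, ref = ref5, alt = alt5,
      cdna = cdna5, n_carriers = carriers5
    )
    other_gene <- function(g, n, exclude = integer()) {
      pool <- setdiff(seq_len(LIT_GENE_LENGTHS[[g]]), exclude)
      pos <- sample(pool, n)
      ref <- vapply(seq_len(n), function(i) sample(AA_ALPHABET, 1), "")
      alt <- vapply(ref, function(a) sample(setdiff(AA_ALPHABET, a), 1), "",
                    USE.NAMES = FALSE)
      tibble(
        gene = g, position = as.integer(pos), ref = ref, alt = alt,
        cdna = sprintf("%dG>A", 3L * pos - 2L), n_carriers = 1L
      )
    }
    uniq <- dplyr::bind_rows(
      scn5a,
      overlap,
      other_gene("SCN4A", 6, exclude = c(103L, 724L)),
      other_gene("SCN10A", 4, exclude = 102L),
      other_gene("SCN1B", 3, exclude = 179L),
      other_gene("SCN3B", 3),
      other_gene("SCN4B", 1)
    )
    stopifnot(nrow(uniq) == 82)
    # 14 variants at AF >= 0.001 carried by 31 individuals:
    # R1193Q (8) + L567Q (7) + one 3-carrier (3) + two 2-carrier (4)
    # + nine singletons (9) = 31
    common_idx <- c(1L, 2L, 3L, 7L, 8L, 13:21)
    af <- numeric(82)
    af[common_idx] <- 10^runif(length(common_idx), log10(1e-3), log10(8e-3))
    rare_idx <- setdiff(seq_len(82), common_idx)
    af[rare_idx] <- 10^runif(length(rare_idx), log10(1e-6), log10(8e-4))
    af[sample(rare_idx, 6)] <- 0 # a few alleles absent from the population db
    uniq$af <- af
    stopifnot(sum(af >= 0.001) == 14, sum(uniq$n_carriers[af >= 0.001]) == 31)
    # correlated six-tool panels: historically reported variants tend to
    # look damaging; common alleles less so
    p_dmg <- ifelse(af >= 0.001, 0.3, 0.75)
    for (tl in prediction_tools()$tool) {
      uniq[[tl]] <- round(tool_score(runif(82) < p_dmg, tl), 4)
    }
    uniq$original_class <- sample(
      c("P", "LP", "VUS"), 82, replace = TRUE, prob = c(0.45, 0.35, 0.2)
    )
    # expand unique variants to carrier rows: 109 slots over 103 ids, the
    # first six ids each carrying a second (different) variant
    rows <- uniq[rep(seq_len(82), uniq$n_carriers), ]
    stopifnot(nrow(rows) == 109)
    rows$case_id <- c(sprintf("L%03d", 1:103), sprintf("L%03d", 1:6))
    transcripts <- c(
      SCN1A = "NM_001165963.1", SCN4A = "NM_000334.3", SCN5A = "NM_198056.2",
      SCN10A = "NM_006514.2", SCN1B = "NM_199037.4", SCN3B = "NM_018400.3",
      SCN4B = "NM_174934.3"
    )
    df <- tibble(
      gene = rows$gene,
      case_id = rows$case_id,
      transcript = unname(transcripts[rows$gene]),
      cdna = rows$cdna,
      protein = paste0(rows$ref, rows$position, rows$alt),
      af = signif(rows$af, 4),
      sift = rows$sift,
      polyphen2_hvar = rows$polyphen2_hvar,
      polyphen2_hdiv = rows$polyphen2_hdiv,
      mutation_assessor = rows$mutation_assessor,
      fathmm = rows$fathmm,
      lrt = rows$lrt,
      original_class = rows$original_class,
      inheritance = "unknown",
      cohort = "case"
    )
    parse_variant_frame(df)
  })
}

#' Synthetic stand-in alignment of the nine VGSC alpha-subunits
#'
#' The real gene-family alignment behind the published paralog
#' conservation scores is not available, so this builds a synthetic
#' paralog family labelled with the nine alpha-subunit gene symbols
#' (SCN1A–SCN5A, SCN8A–SCN11A), anchored on SCN9A. It is constructed so
#' that (a) every missense variant of the packaged cohort and literature
#' tables finds its expected reference residue, and (b) SCN10A carries one
#' leading gap, which places SCN10A residue 102 and SCN4A residue 103 in
#' the same alignment column — the shared-paralog-position pair observed
#' in the cohort. It is a reconstruction for pipeline demonstration and
#' testing, not the published alignment, and its conservation scores are
#' not comparable to published ones.
#'
#' @param seed Integer seed for the synthetic background family.
#' @return A [paralog_alignment()] of 9 rows.
#' @export
synthetic_vgsc_alignment <- function(seed = 1309L) {
  genes <- c("SCN1A", "SCN2A", "SCN3A", "SCN4A", "SCN5A",
             "SCN8A", "SCN9A", "SCN10A", "SCN11A")
  transcripts <- c(
    SCN1A = "NM_001165963.1", SCN2A = "synthetic", SCN3A = "NM_006922.3",
    SCN4A = "NM_000334.3", SCN5A = "NM_198056.2", SCN8A = "synthetic",
    SCN9A = "ENST00000409672", SCN10A = "NM_006514.2", SCN11A = "synthetic"
  )
  L <- 2050L
  fam <- withr::with_seed(seed, {
    ancestral <- sample(AA_ALPHABET, L, replace = TRUE)
    conserved <- sort(sample.int(L, round(0.35 * L)))
    rate <- rep(0.45, L)
    rate[conserved] <- 0.03
    lapply(genes, function(g) mutate_sequence(ancestral, rate))
  })
  names(fam) <- genes
  # one leading gap in SCN10A: its residue p sits in column p + 1
  fam$SCN10A <- c("-", fam$SCN10A[-1])
  # plant the reference residues of the packaged variant tables
  plants <- dplyr::bind_rows(
    cohort_variants_table()[, c("gene", "position", "ref_aa", "kind")],
    literature_variants_synthetic()[, c("gene", "position", "ref_aa", "kind")]
  )
  plants <- dplyr::filter(
    dplyr::distinct(plants),
    .data$kind == "missense", .data$gene %in% genes
  )
  for (i in seq_len(nrow(plants))) {
    g <- plants$gene[i]
    col <- plants$position[i] + if (g == "SCN10A") 1L else 0L
    fam[[g]][col] <- plants$ref_aa[i]
  }
  paralog_alignment(
    tibble(
      gene_id = genes,
      transcript_id = unname(transcripts[genes]),
      aligned = vapply(fam, paste, "", collapse = "")
    ),
    reference_gene = "SCN9A"
  )
}

#' Rejection rate of the conserved-shift t-test on simulated data
#'
#' Repeatedly simulates a paralog family and a case/control variant set,
#' scores every variant's alignment column on the family conservation
#' profile, runs the case-versus-control Welch t-test, and reports the
#' fraction of replicates rejecting at `alpha`. With
#' `enrichment_delta = 0` this estimates the test's type-I error under the
#' generative model; with a positive delta it estimates power.
#'
#' @param n_rep Number of replicates.
#' @param alpha Rejection level.
#' @param seed Base seed; replicate r uses `seed + r` for its config.
#' @param ... [sim_config()] parameters (`enrichment_delta`, `n_case`,
#'   `n_control`, `sequence_length`, ...).
#' @return A one-row tibble with `rejection_rate`, `n_rep`, `alpha`.
#' @export
conserved_shift_rejection_rate <- function(n_rep = 100, alpha = 0.001, seed, ...) {
  if (missing(seed)) stop_config("a base seed is required")
  reject <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(seed = seed + r, ...)
    fam <- simulate_family(cfg)
    var <- simulate_variants(cfg, fam)
    prof <- parazscore_profile(fam$alignment)
    map <- alignment_index_map(fam$alignment)
    var$parazscore <- score_variant_position(prof, map, var$gene, var$position)
    p <- parazscore_ttest(var)$p_value
    reject[r] <- p < alpha
  }
  tibble(rejection_rate = mean(reject), n_rep = n_rep, alpha = alpha)
}

#' Summarize a cohort variant table
#'
#' Case-level and variant-level descriptive counts: unique variants,
#' distinct cases, variants passing the rarity rule, cases with an
#' abnormal hippocampus, and cases younger than six months (ages parsed
#' with [parse_age_days()], 6 months = 182.6 days).
#'
#' @param records A variant tibble (e.g. [cohort_variants_table()]).
#' @param rare_threshold Allele-frequency rarity threshold.
#' @return A one-row tibble of counts.
#' @export
cohort_summary <- function(records, rare_threshold = 0.001) {
  records <- as_tibble(records)
  uniq <- deduplicate_variants(records)
  af_eff <- ifelse(is.na(uniq$af), 0, uniq$af)
  per_case <- dplyr::distinct(records, .data$case_id, .keep_all = TRUE)
  age_days <- if ("age" %in% names(records)) parse_age_days(per_case$age) else rep(NA_real_, nrow(per_case))
  hippo <- if ("hippocampus" %in% names(records)) per_case$hippocampus else rep(NA_character_, nrow(per_case))
  tibble(
    n_rows = nrow(records),
    n_unique_variants = nrow(uniq),
    n_cases = dplyr::n_distinct(records$case_id),
    n_rare_variants = sum(af_eff < rare_threshold),
    n_hippocampal_abnormal = sum(!is.na(hippo) & hippo == "abnormal"),
    n_under_6_months = sum(!is.na(age_days) & age_days < 6 * 30.44)
  )
}

#' Write the packaged fixture tables
#'
#' Writes the cohort variant table and the synthetic literature
#' reconstruction as TSVs with provenance comment headers, in the dialect
#' [read_variant_table()] consumes.
#'
#' @param dir Output directory (created if needed).
#' @return Character vector of the two paths, invisibly.
#' @export
make_fixture_tables <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    list(
      file = "cohort_variants.tsv",
      data = cohort_variants_table(),
      header = c(
        "# Cohort variant table: 11 unique voltage-gated sodium channel variants",
        "# in 10 sudden-unexpected-death-in-pediatrics cases (12 rows; one case",
        "# carries two variants in cis, two siblings share one nonsense variant).",
        "# parazscore_published / acmg_published are the original expert",
        "# annotations, carried as descriptive inputs only."
      )
    ),
    list(
      file = "literature_variants_synthetic.tsv",
      data = literature_variants_synthetic(),
      header = c(
        "# SYNTHETIC reconstruction of the literature variant set: the real",
        "# per-variant supplementary table is unpublished; this table realizes",
        "# its printed marginal counts (82 variants / 103 individuals / 109",
        "# rows; 14 variants with AF >= 0.001 carried by 31 individuals; top",
        "# recurrence 8) with synthesized positions, scores and frequencies.",
        "# Not real data."
      )
    )
  )
  paths <- vapply(specs, function(s) {
    path <- file.path(dir, s$file)
    writeLines(s$header, path)
    df <- s$data
    df$row <- NULL
    out <- as.data.frame(df)
    suppressWarnings(
      readr::write_tsv(out, path, na = ".", append = TRUE, col_names = TRUE)
    )
    path
  }, "")
  invisible(paths)
}

#' Path to a packaged example file
#'
#' @param file File name under the package's `extdata/`; `NULL` lists the
#'   available files.
#' @return A path (or a character vector of file names).
#' @export
paravar_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "paravar")))
  }
  path <- system.file("extdata", file, package = "paravar")
  if (path == "") stop_value(paste0("no packaged file called '", file, "'"))
  path
}
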