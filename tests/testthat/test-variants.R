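test_that("protein HGVS parses one-letter, three-letter and stop forms", {
  p <- parse_protein_hgvs(c(
    "p.Leu1296Met", "L1296M", "W179*", "p.Trp179Ter", "p.(Glu1308Asp)"
  ))
  expect_equal(p$ref_aa, c("L", "L", "W", "W", "E"))
  expect_equal(p$position, c(1296L, 1296L, 179L, 179L, 1308L))
  expect_equal(p$alt_aa, c("M", "M", "*", "*", "D"))
  expect_equal(p$kind, c("missense", "missense", "nonsense", "nonsense", "missense"))
  # errors name the offending token
  expect_error(parse_protein_hgvs("L61"), "L61", class = "paravar_parse_error")
  expect_error(parse_protein_hgvs("p.Xyz12Met"), class = "paravar_parse_error")
  expect_error(parse_protein_hgvs("A10A"), class = "paravar_parse_error")
})

test_that("variant TSV reader enforces schema and value ranges", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene\tcdna\tprotein\taf\tcohort\tcase_id",
    "G1\t10A>T\tA4V\t0.5\tcase\tc1",
    "G1\t13A>T\tW5*\t.\tcase\tc2"
  ), path)
  v <- read_variant_table(path)
  expect_equal(nrow(v), 2)
  expect_true(is.na(v$af[2])) # blank AF stays missing, distinct from 0
  expect_equal(v$kind, c("missense", "nonsense"))
  expect_equal(v$row, 1:2)

  writeLines("gene\tcdna\n", path)
  expect_error(read_variant_table(path), class = "paravar_schema_error")

  writeLines(c(
    "gene\tcdna\tprotein\taf\tcohort",
    "G1\t10A>T\tA4V\t1.5\tcase"
  ), path)
  expect_error(read_variant_table(path), class = "paravar_value_error")

  writeLines(c(
    "gene\tcdna\tprotein\taf\tcohort\tsplice_likelihood",
    "G1\t10+1G>C\t.\t0.001\tcase\t."
  ), path)
  expect_error(read_variant_table(path), class = "paravar_consistency_error")
})

test_that("deduplication keys on (gene, cdna) and counts distinct carriers", {
  df <- tibble::tibble(
    gene = c("SCN1B", "SCN1B", "G1"),
    cdna = c("536G>A", "536G>A", "536G>A"),
    protein = c("W179*", "W179*", "A4V"),
    af = 1e-5, cohort = "case",
    case_id = c("Case9", "Case10", "x"),
    ref_aa = c("W", "W", "A"), position = c(179L, 179L, 4L),
    alt_aa = c("*", "*", "V"), kind = c("nonsense", "nonsense", "missense"),
    row = 1:3
  )
  u <- deduplicate_variants(df)
  expect_equal(nrow(u), 2)
  expect_equal(u$n_carriers, c(2L, 1L))
  expect_equal(u$carriers[1], "Case10,Case9")

  # conflicting protein annotation under one key is rejected
  bad <- df
  bad$protein[2] <- "W179C"
  bad$alt_aa[2] <- "C"
  bad$kind[2] <- "missense"
  expect_error(deduplicate_variants(bad), class = "paravar_consistency_error")

  # all-distinct rows stay distinct
  solo <- random_records(5, seed = 2)
  expect_equal(nrow(deduplicate_variants(solo)), 5)
})

test_that("deduplication matches a nested-loop oracle on synthetic duplicates", {
  withr::with_seed(77, {
    df <- tibble::tibble(
      gene = sample(c("A", "B", "C"), 60, replace = TRUE),
      cdna = sprintf("%dG>A", sample(1:12, 60, replace = TRUE)),
      case_id = sprintf("id%d", sample(1:25, 60, replace = TRUE))
    )
  })
  df$protein <- NA
  df$af <- 0
  df$cohort <- "case"
  df$ref_aa <- NA
  df$position <- NA_integer_
  df$alt_aa <- NA
  df$kind <- "splice"
  df$row <- seq_len(60)
  u <- deduplicate_variants(df)
  o <- dedup_oracle(df)
  expect_equal(nrow(u), nrow(o))
  expect_equal(paste(u$gene, u$cdna, sep = "|"), o$key)
  expect_equal(u$n_carriers, o$n_carriers)
  # carrier counts add back to the number of (key, case) incidences
  expect_equal(sum(u$n_rows), nrow(df))
})

ann_fixture <- function() {
  aln <- toy_alignment(data.frame(
    gene_id = c("GA", "GB", "GC"),
    aligned = c("WACDE", "-ACDF", "WACQE")
  ))
  domains <- tibble::tibble(
    gene = "GA", domain = "DI", segment = "S4", start = 2L, end = 3L
  )
  variants <- tibble::tibble(
    gene = c("GA", "GB", "GA", "GX", "GA"),
    cdna = sprintf("%dG>A", 1:5),
    protein = c("A2V", "C2A", "W1*", "A9V", "D4E"),
    af = 1e-5, cohort = "case", case_id = sprintf("c%d", 1:5),
    splice_likelihood = NA_real_
  )
  variants <- paravar:::parse_variant_frame(variants)
  list(aln = aln, domains = domains, variants = variants)
}

test_that("annotation maps missense only, with regions from the architecture", {
  f <- ann_fixture()
  prof <- parazscore_profile(f$aln, min_nongap = 2)
  ann <- annotate_variants(f$variants, f$aln, profile = prof, domains = f$domains)
  # GA A2V -> column 2, transmembrane (S4 range 2..3)
  expect_equal(ann$column[1], 2L)
  expect_equal(ann$region[1], "transmembrane")
  # GB has a leading gap: residue 2 (C) -> column 3
  expect_equal(ann$column[2], 3L)
  expect_equal(ann$region[2], "unknown") # no architecture for GB
  # nonsense: no column, region unknown even inside a configured gene
  expect_true(is.na(ann$column[3]))
  expect_equal(ann$region[3], "unknown")
  # gene absent from the alignment: gracefully unmapped
  expect_true(is.na(ann$column[4]))
  # extramembrane when outside every segment
  expect_equal(ann$region[5], "extramembrane")
  # parazscore equals the column score
  expect_equal(ann$parazscore[1], prof$parazscore[2])
})

test_that("reference mismatches error, or are reported under skip_mismatch", {
  f <- ann_fixture()
  prof <- parazscore_profile(f$aln, min_nongap = 2)
  bad <- f$variants
  bad$protein[1] <- "C2V"
  bad$ref_aa[1] <- "C"
  expect_error(
    annotate_variants(bad, f$aln, profile = prof),
    class = "paravar_mismatch_error"
  )
  ann <- annotate_variants(bad, f$aln, profile = prof, skip_mismatch = TRUE)
  expect_true(is.na(ann$column[1]))
  expect_match(ann$mismatch[1], "reference mismatch")
  # position beyond gene length
  far <- f$variants
  far$position[1] <- 99L
  expect_error(
    annotate_variants(far, f$aln, profile = prof),
    class = "paravar_coordinate_error"
  )
})

test_that("annotation is idempotent and order-independent", {
  f <- ann_fixture()
  prof <- parazscore_profile(f$aln, min_nongap = 2)
  a1 <- annotate_variants(f$variants, f$aln, profile = prof, domains = f$domains)
  a2 <- annotate_variants(a1, f$aln, profile = prof, domains = f$domains)
  expect_equal(a1, a2)
  perm <- c(3, 1, 5, 2, 4)
  a3 <- annotate_variants(f$variants[perm, ], f$aln, profile = prof, domains = f$domains)
  expect_equal(a3$column, a1$column[perm])
  expect_equal(a3$parazscore, a1$parazscore[perm])
})

test_that("paralog matches pair cross-gene variants sharing a column", {
  f <- ann_fixture()
  prof <- parazscore_profile(f$aln, min_nongap = 2)
  ann <- annotate_variants(f$variants, f$aln, profile = prof)
  rep <- find_paralog_matches(ann)
  # GA A2V (column 2) has no partner; GB C2A is at column 3; GA D4E column 4
  expect_equal(nrow(rep$pairs), 0)

  # planted cross-gene pair at one column
  planted <- ann_fixture()$variants[1:2, ]
  planted$protein <- c("C3A", "C2A") # GA residue 3 = column 3; GB residue 2 = column 3
  planted$ref_aa <- "C"
  planted$position <- c(3L, 2L)
  planted$alt_aa <- "A"
  ann2 <- annotate_variants(planted, f$aln, profile = prof)
  rep2 <- find_paralog_matches(ann2)
  expect_equal(nrow(rep2$pairs), 1)
  expect_setequal(c(rep2$pairs$gene1, rep2$pairs$gene2), c("GA", "GB"))

  # same gene, same column: excluded
  same_gene <- planted
  same_gene$gene <- "GA"
  same_gene$protein <- "C3A"
  same_gene$position <- 3L
  ann3 <- annotate_variants(same_gene, f$aln, profile = prof)
  expect_equal(nrow(find_paralog_matches(ann3)$pairs), 0)

  # single variant: no matches
  expect_equal(nrow(find_paralog_matches(ann2[1, ])$pairs), 0)

  # known disease positions are an explicit optional input
  rep4 <- find_paralog_matches(ann2, known_disease_positions = 3L)
  expect_equal(nrow(rep4$at_known_positions), 2)
  expect_false(rep$known_positions_supplied)
})

test_that("domain table reader validates ranges", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene\tdomain\tsegment\tstart\tend",
    "G1\tDI\tS1\t5\t10",
    "G1\tDI\tS2\t8\t12"
  ), path)
  expect_error(read_domain_table(path), class = "paravar_consistency_error")
  writeLines(c(
    "gene\tdomain\tsegment\tstart\tend",
    "G1\tDI\tS1\t5\t10",
    "G1\tDI\tS2\t11\t12"
  ), path)
  d <- read_domain_table(path)
  expect_equal(nrow(d), 2)
})
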