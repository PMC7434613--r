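test_that("simulation config validates its inputs", {
  expect_error(sim_config(), class = "paravar_config_error")
  expect_error(sim_config(seed = 1, fraction_conserved = 1.4),
    class = "paravar_config_error"
  )
  expect_error(sim_config(seed = 1, sequence_length = 0),
    class = "paravar_config_error"
  )
  expect_error(sim_config(seed = 1, af_weights = c(0.5, 0.5)),
    class = "paravar_config_error"
  )
})

test_that("family simulation is seeded, sized and rate-faithful", {
  cfg <- sim_config(n_paralogs = 5, sequence_length = 200,
                    fraction_conserved = 0.3, seed = 7)
  fam <- simulate_family(cfg)
  expect_equal(n_columns(fam$alignment), 200L)
  expect_equal(length(fam$conserved_columns), 60L) # 0.3 * 200
  fam2 <- simulate_family(cfg)
  expect_identical(fam$alignment$aligned, fam2$alignment$aligned)
  expect_identical(fam$conserved_columns, fam2$conserved_columns)

  # zero substitution rates: all rows identical, every column fully conserved
  frozen <- simulate_family(sim_config(
    n_paralogs = 4, sequence_length = 50,
    rate_conserved = 0, rate_variable = 0, seed = 2
  ))
  expect_equal(length(unique(frozen$alignment$aligned)), 1)
  expect_error(parazscore_profile(frozen$alignment),
    class = "paravar_profile_error" # all-identical columns: zero variance
  )
})

test_that("planted conserved columns are recoverable from the profile", {
  cfg <- sim_config(n_paralogs = 9, sequence_length = 300,
                    rate_conserved = 0.02, rate_variable = 0.5, seed = 21)
  fam <- simulate_family(cfg)
  prof <- parazscore_profile(fam$alignment)
  sens <- mean(prof$parazscore[fam$conserved_columns] > 0)
  expect_gte(sens, 0.9)
  # a variant planted on a fully conserved column scores above 0
  full <- which(prof$raw == 1 & seq_len(300) %in% fam$conserved_columns)[1]
  expect_gt(prof$parazscore[full], 0)
})

test_that("variant simulation is consistent with its family", {
  cfg <- sim_config(n_paralogs = 6, sequence_length = 120,
                    n_case = 40, n_control = 80, seed = 9)
  fam <- simulate_family(cfg)
  var <- simulate_variants(cfg, fam)
  expect_equal(sum(var$cohort == "case"), 40)
  expect_equal(sum(var$cohort == "control"), 80)
  expect_true(all(var$af >= 0 & var$af <= 1))
  expect_true(all(var$kind == "missense"))
  # construction guarantees reference consistency: zero mismatches
  ann <- annotate_variants(var, fam$alignment)
  expect_true(all(is.na(ann$mismatch)))
  expect_true(all(!is.na(ann$column)))
  # determinism
  var2 <- simulate_variants(cfg, fam)
  expect_identical(var, var2)
})

test_that("delta = 0 gives cases the control positional distribution", {
  cfg <- sim_config(n_paralogs = 5, sequence_length = 100,
                    n_case = 5000, n_control = 5000,
                    enrichment_delta = 0, seed = 31)
  fam <- simulate_family(cfg)
  var <- simulate_variants(cfg, fam)
  ks <- suppressWarnings(stats::ks.test(
    var$position[var$cohort == "case"],
    var$position[var$cohort == "control"]
  ))
  expect_gt(ks$p.value, 0.01)
})

test_that("allele-frequency mixture straddles the 0.001 threshold", {
  cfg <- sim_config(n_case = 0, n_control = 4000, seed = 17)
  fam <- simulate_family(cfg)
  var <- simulate_variants(cfg, fam)
  frac_common <- mean(var$af >= 1e-3)
  expect_gt(frac_common, 0.05)
  expect_lt(frac_common, 0.2) # nominal weight 0.1
  expect_gt(mean(var$af < 1e-4), 0.5) # nominal weight 0.7
})

test_that("synthetic domains tile without overlap in the documented schema", {
  fam <- simulate_family(sim_config(n_paralogs = 3, sequence_length = 150, seed = 4))
  dom <- simulate_domains(fam)
  expect_named(dom, c("gene", "domain", "segment", "start", "end"))
  for (g in unique(dom$gene)) {
    d <- dom[dom$gene == g, ]
    d <- d[order(d$start), ]
    expect_true(all(d$start <= d$end))
    if (nrow(d) > 1) expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }
  expect_true(all(grepl("^D(I|II|III|IV)$", dom$domain)))
  expect_true(all(grepl("^S[1-6]$", dom$segment)))
})

test_that("packaged fixtures regenerate byte-identically from code", {
  dir <- withr::local_tempdir()
  paths <- make_fixture_tables(dir)
  for (p in paths) {
    shipped <- paravar_example(basename(p))
    expect_identical(readLines(p), readLines(shipped))
  }
})

test_that("cohort fixture carries the published per-case structure", {
  ct <- read_variant_table(paravar_example("cohort_variants.tsv"))
  expect_equal(nrow(ct), 12)
  expect_equal(dplyr::n_distinct(ct$case_id), 10)
  expect_equal(nrow(deduplicate_variants(ct)), 11)
  expect_true(all(ct$af >= 0 & ct$af <= 1))
  # one splice row, two nonsense rows (the shared sibling variant)
  expect_equal(sum(ct$kind == "splice"), 1)
  expect_equal(sum(ct$kind == "nonsense"), 2)
})

test_that("the synthetic family stand-in annotates every packaged missense row", {
  aln <- synthetic_vgsc_alignment()
  expect_equal(nrow(aln), 9)
  expect_equal(attr(aln, "reference_gene"), "SCN9A")
  ct <- cohort_variants_table()
  ann <- annotate_variants(ct, aln)
  miss <- ann$kind == "missense"
  expect_true(all(!is.na(ann$column[miss & ann$gene %in% aln$gene_id])))
  expect_true(all(is.na(ann$column[!miss])))
  # the two bolded cohort variants share one alignment index position
  m <- find_paralog_matches(ann)
  expect_equal(nrow(m$pairs), 1)
  expect_setequal(c(m$pairs$gene1, m$pairs$gene2), c("SCN4A", "SCN10A"))
  # literature reconstruction also annotates cleanly for alpha-subunit genes
  lit <- literature_variants_synthetic()
  lann <- annotate_variants(lit, aln, skip_mismatch = TRUE)
  expect_true(all(is.na(lann$mismatch)))
})
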