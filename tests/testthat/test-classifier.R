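panel_row <- function(n_damaging, n_available = 6) {
  # scores on the damaging/benign side of each tool's default threshold
  tools <- prediction_tools()
  damaging_side <- c(0.01, 0.9, 0.9, 3, -5, 1e-4)
  benign_side <- c(0.8, 0.1, 0.1, 0.5, 5, 0.5)
  x <- ifelse(seq_len(6) <= n_damaging, damaging_side, benign_side)
  x[seq_len(6) > n_available] <- NA
  stats::setNames(as.list(x), tools$tool)
}

record_with_panel <- function(n_damaging, n_available = 6, af = 1e-5,
                              kind = "missense", inheritance = "unknown",
                              splice_likelihood = NA_real_) {
  df <- tibble::tibble(
    gene = "G", cdna = "1A>T",
    protein = if (kind == "nonsense") "W10*" else if (kind == "splice") NA_character_ else "A10V",
    af = af, cohort = "case", case_id = "c1",
    inheritance = inheritance, splice_likelihood = splice_likelihood,
    kind = kind
  )
  for (tl in names(panel_row(0))) df[[tl]] <- panel_row(n_damaging, n_available)[[tl]]
  df
}

test_that("in-silico consensus applies the 4-of-6 majority rule", {
  df <- dplyr::bind_rows(
    record_with_panel(4), # >= 4 of 6 -> damaging
    record_with_panel(6),
    record_with_panel(3), # boundary below the rule -> conflicting
    record_with_panel(0), # <= 2 -> benign
    record_with_panel(2),
    record_with_panel(2, n_available = 3), # too few tools -> insufficient
    record_with_panel(4, n_available = 4) # 4 of 4 -> damaging
  )
  out <- insilico_consensus(df)
  expect_equal(
    out$insilico,
    c("damaging", "damaging", "conflicting", "benign", "benign",
      "insufficient", "damaging")
  )
  expect_true(all(out$n_damaging <= out$n_available))
  bad <- record_with_panel(0)
  bad$sift <- 2
  expect_error(insilico_consensus(bad), class = "paravar_value_error")
})

test_that("splice rule has an inclusive 50% boundary", {
  expect_equal(splice_class(c(100, 50, 49.9, 10)),
    c("damaging", "damaging", "not_damaging", "not_damaging")
  )
  expect_error(splice_class(120), class = "paravar_value_error")
})

test_that("ACMG-lite reproduces the mechanically determined classes", {
  # nonsense + rare (the shared sibling stop-gain) -> LP
  w <- classify_variants(record_with_panel(0, n_available = 0,
    af = 8.19e-6, kind = "nonsense"
  ))
  expect_equal(w$acmg_class, "LP")
  expect_true("PVS1_like" %in% w$evidence[[1]])

  # rare damaging missense with nothing else -> VUS
  a <- classify_variants(record_with_panel(6, af = 2.44e-5))
  expect_equal(a$acmg_class, "VUS")
  expect_setequal(a$evidence[[1]], c("PM2_like", "PP3_like"))

  # frequency at or above 0.001 fires strong benign -> LB
  b <- classify_variants(record_with_panel(3, af = 0.002))
  expect_equal(b$acmg_class, "LB")
  # ... and B when the panel consensus is also benign
  b2 <- classify_variants(record_with_panel(0, af = 0.002))
  expect_equal(b2$acmg_class, "B")

  # de novo + nonsense: two strong -> P
  p <- classify_variants(record_with_panel(0, n_available = 0,
    af = 0, kind = "nonsense", inheritance = "de_novo"
  ))
  expect_equal(p$acmg_class, "P")

  # strong both directions -> VUS flagged conflicting
  cf <- classify_variants(record_with_panel(0, n_available = 0,
    af = 0.002, kind = "nonsense"
  ))
  expect_equal(cf$acmg_class, "VUS")
  expect_true(cf$conflicting)

  # splice likelihood >= 50 supports pathogenic but stays VUS when rare
  sp <- classify_variants(tibble::tibble(
    gene = "G", cdna = "10+1G>C", protein = NA, af = 1.22e-5,
    cohort = "case", case_id = "c", inheritance = "unknown",
    splice_likelihood = 100, kind = "splice"
  ))
  expect_equal(sp$acmg_class, "VUS")
  expect_true("PP3_like" %in% sp$evidence[[1]])

  # AF = 0 (absent from gnomAD) passes the rarity rule
  z <- classify_variants(record_with_panel(0, n_available = 0, af = 0, kind = "nonsense"))
  expect_true("PM2_like" %in% z$evidence[[1]])
  expect_equal(z$acmg_class, "LP")
})

test_that("cohort table classes match the printed mechanically-determined rows", {
  ct <- classify_variants(cohort_variants_table())
  mech <- ct$kind == "nonsense" | ct$acmg_published == "VUS"
  expect_true(all(ct$acmg_class[mech] == ct$acmg_published[mech]))
  # expert-evidence rows are deliberately not reproduced (carried as input)
  expect_true(all(ct$acmg_class %in% c("P", "LP", "VUS", "LB", "B")))
})

test_that("classification is deterministic, total, and monotone", {
  df <- random_records(300, seed = 41)
  c1 <- classify_variants(df)
  perm <- withr::with_seed(8, sample(nrow(df)))
  c2 <- classify_variants(df[perm, ])
  expect_equal(c2$acmg_class, c1$acmg_class[perm])
  expect_true(all(!is.na(c1$acmg_class)))
  expect_true(all(c1$acmg_class %in% c("P", "LP", "VUS", "LB", "B")))

  # adding pathogenic evidence (de novo) never moves toward benign
  dn <- df
  dn$inheritance <- "de_novo"
  cdn <- classify_variants(dn)
  expect_true(all(acmg_rank(cdn$acmg_class) >= acmg_rank(c1$acmg_class)))

  # raising AF above the threshold never moves toward pathogenic
  hi <- df
  hi$af <- pmin(1, ifelse(is.na(hi$af), 0.002, hi$af * 10 + 0.001))
  chi <- classify_variants(hi)
  expect_true(all(acmg_rank(chi$acmg_class) <= acmg_rank(c1$acmg_class)))
})

test_that("re-evaluation reports class and AF-filter counts", {
  lit <- literature_variants_synthetic()
  rep <- reevaluate_variants(lit)
  expect_equal(rep$af_filter$n_variants, 82)
  expect_equal(rep$af_filter$n_carriers, 109)
  expect_equal(rep$af_filter$n_variants_ge, 14)
  expect_equal(rep$af_filter$n_carriers_ge, 31)
  expect_equal(sum(rep$by_class$n_variants), 82)
  expect_false(is.null(rep$before_after))
  g <- glance(rep)
  expect_equal(g$n_variants_af_ge, 14)

  empty <- reevaluate_variants(lit[0, ])
  expect_equal(empty$af_filter$n_variants, 0)
  expect_equal(nrow(empty$by_class), 0)

  # synthetic AF values straddling the threshold: counts match a direct scan
  withr::with_seed(12, {
    df <- random_records(80, seed = 13)
    df$af <- 10^runif(80, -5, -2)
  })
  r <- reevaluate_variants(df)
  expect_equal(r$af_filter$n_variants_ge, sum(df$af >= 0.001))
})
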