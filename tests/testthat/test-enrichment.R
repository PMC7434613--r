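test_that("Welch t matches the closed form and base R", {
  # two-point groups: closed-form t = (mx - my) / sqrt(vx/2 + vy/2)
  x <- c(1, 3)
  y <- c(10, 14)
  w <- welch_ttest(x, y)
  se <- sqrt(var(x) / 2 + var(y) / 2)
  expect_equal(w$statistic, (mean(x) - mean(y)) / se, tolerance = 1e-12)
  tt <- t.test(x, y) # independent cross-check
  expect_equal(w$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(w$p_value, tt$p.value, tolerance = 1e-12)

  # identical groups: t = 0, p = 1
  same <- welch_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # a +10 shift on three points is decisive
  shifted <- welch_ttest(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shifted$p_value, 0.01)

  # degenerate groups are named in the error
  expect_error(welch_ttest(c(1, 1), c(1, 2), case_label = "case"),
    "case", class = "paravar_stats_error"
  )
  expect_error(welch_ttest(c(1), c(1, 2)), class = "paravar_stats_error")
})

test_that("data-frame t-test interface splits by cohort", {
  df <- tibble::tibble(
    parazscore = c(1, 2, 3, 11, 12, 13),
    cohort = rep(c("case", "control"), each = 3)
  )
  r <- parazscore_ttest(df)
  expect_equal(r$test, "parazscore_welch_t")
  expect_equal(r$estimate, -10)
  td <- tidy(r)
  expect_equal(td$p.value, r$p_value)
  g <- glance(r)
  expect_true(g$significant)
})

test_that("Fisher kernel equals exhaustive hypergeometric enumeration", {
  # the worked micro-example: margins (2,2)/(2,2), diagonal table
  expect_equal(
    fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE))$p_value,
    1 / 3,
    tolerance = 1e-12
  )
  # random tables with margins <= 20, against the enumeration oracle and
  # against stats::fisher.test
  withr::with_seed(101, {
    for (i in 1:200) {
      tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
      if (sum(tab[1, ]) > 20 || sum(tab[2, ]) > 20) next
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      p <- fisher_exact_2x2(tab)$p_value
      expect_equal(p, fisher_oracle(tab), tolerance = 1e-12)
      expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    }
  })
  # zero margin: uninformative, p = 1 with a warning
  expect_warning(
    z <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
    "zero margin"
  )
  expect_equal(z$p_value, 1)
})

test_that("conserved-site and transmembrane Fisher tests share the kernel", {
  df <- tibble::tibble(
    parazscore = c(1.2, 0.8, 0.5, -0.3, -1, -0.2, 0.4, -0.9),
    region = c("transmembrane", "transmembrane", "extramembrane", "transmembrane",
               "extramembrane", "extramembrane", "unknown", "extramembrane"),
    pathogenic = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  fc <- fisher_conserved(df)
  expect_equal(unname(fc$table[1, ]), c(4, 0)) # pathogenic: 4 conserved, 0 not
  expect_equal(fc$p_value, fisher_oracle(fc$table), tolerance = 1e-12)

  ft <- fisher_transmembrane(df)
  expect_equal(sum(ft$table), 7) # the 'unknown' row is dropped
  expect_equal(ft$p_value, fisher_exact_2x2(ft$table)$p_value)

  # label auto-derivation precedence: explicit > pathogenic col > acmg_class
  df2 <- dplyr::mutate(df, acmg_class = ifelse(pathogenic, "LP", "VUS"))
  df2$pathogenic <- NULL
  fc2 <- fisher_conserved(df2)
  expect_equal(fc2$table, fc$table)
  expect_error(
    fisher_conserved(dplyr::select(df, parazscore)),
    class = "paravar_schema_error"
  )

  # degenerate: everything transmembrane gives a zero margin and p = 1
  all_tm <- dplyr::mutate(df[df$region == "transmembrane", ], pathogenic = c(TRUE, TRUE, FALSE))
  expect_warning(p1 <- fisher_transmembrane(all_tm))
  expect_equal(p1$p_value, 1)
})

test_that("permutation p follows the add-one estimator and is reproducible", {
  # observed above every null draw: minimal attainable p = 1/(B+1)
  r <- copositioning_test(
    c(5, 5, 5), pool = c(1, 2, 3, 4), target_positions = c(5),
    mode = "target", B = 999, seed = 7
  )
  expect_equal(r$statistic, 3)
  expect_equal(r$p_value, 1 / 1000)
  expect_equal(r$permutation$n_ge, 0)

  r2 <- copositioning_test(
    c(5, 5, 5), pool = c(1, 2, 3, 4), target_positions = c(5),
    mode = "target", B = 999, seed = 7
  )
  expect_identical(r$permutation$null_draws, r2$permutation$null_draws)
  expect_equal(r$p_value, (1 + r$permutation$n_ge) / (1 + r$permutation$B))
  expect_gt(r$p_value, 0)

  # pairs mode: cross-gene pairs only
  r3 <- copositioning_test(
    c(9, 9, 9), pool = rep(1:20, 3), mode = "pairs",
    genes = c("A", "A", "B"), B = 199, seed = 3
  )
  expect_equal(r3$statistic, 2) # (A1,B), (A2,B); the A-A pair is excluded

  expect_error(
    copositioning_test(1:5, pool = 1:3, target_positions = 1,
      mode = "target", B = 99, replace = FALSE
    ),
    class = "paravar_sampling_error"
  )
  expect_error(
    copositioning_test(1:3, pool = 1:5, target_positions = 1, B = 50),
    class = "paravar_value_error"
  )
  expect_error(
    copositioning_test(1:3, pool = 1:5, B = 99, mode = "target"),
    class = "paravar_value_error"
  )
})

test_that("tiny permutation instance matches complete enumeration", {
  # pool of 4 columns, 2 case draws with replacement, target set {1}:
  # exact tail probabilities from the 16 equally likely draws
  pool <- c(1, 2, 3, 4)
  target <- 1
  exact_tail <- function(obs) {
    draws <- expand.grid(a = pool, b = pool)
    stat <- (draws$a %in% target) + (draws$b %in% target)
    mean(stat >= obs)
  }
  for (case_cols in list(c(1, 1), c(1, 2), c(3, 4))) {
    obs <- sum(case_cols %in% target)
    r <- copositioning_test(case_cols, pool,
      target_positions = target,
      mode = "target", B = 20000, seed = 99
    )
    # the add-one estimator converges on the enumerated tail probability
    expect_lt(abs(r$p_value - exact_tail(obs)), 0.01)
  }
})

test_that("permutation p is monotone non-increasing in the observed statistic", {
  pool <- rep(1:10, 5)
  ps <- vapply(0:3, function(k) {
    cols <- c(rep(1, k), rep(99, 3 - k)) # 99 never in pool or target
    copositioning_test(cols, pool,
      target_positions = 1:2, mode = "target", B = 499, seed = 5
    )$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})
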