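# Independent oracles and small fixture builders used across the suite.

toy_alignment <- function(rows, reference = rows$gene_id[1]) {
  paralog_alignment(rows, reference_gene = reference)
}

# Exhaustive two-sided Fisher p for a 2x2 table: enumerate the whole
# hypergeometric support and compute each table's probability from the
# combinatorial identity choose(r1, k) choose(r2, c1 - k) / choose(N, c1),
# independent of stats::dhyper.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); N <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(N, c1)
  probs <- exp(logp)
  p_obs <- probs[support == tab[1, 1]]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Enumerate every global alignment of two short strings recursively and
# return the maximum score under linear gap costs.
best_pairwise_score <- function(x, y, match = 1, mismatch = -1, gap = -1) {
  xs <- strsplit(x, "")[[1]]
  ys <- strsplit(y, "")[[1]]
  rec <- function(i, j) {
    if (i > length(xs) && j > length(ys)) return(0)
    best <- -Inf
    if (i <= length(xs) && j <= length(ys)) {
      s <- if (xs[i] == ys[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= length(xs)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(ys)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# Hash-free nested-loop grouping of variant rows by (gene, cdna).
dedup_oracle <- function(df) {
  seen <- list()
  order_keys <- character(0)
  for (i in seq_len(nrow(df))) {
    k <- paste(df$gene[i], df$cdna[i], sep = "|")
    if (is.null(seen[[k]])) {
      seen[[k]] <- character(0)
      order_keys <- c(order_keys, k)
    }
    seen[[k]] <- union(seen[[k]], df$case_id[i])
  }
  data.frame(
    key = order_keys,
    n_carriers = vapply(order_keys, function(k) length(seen[[k]]), integer(1)),
    row.names = NULL
  )
}

# Random variant records for property tests of the classifier.
random_records <- function(n, seed) {
  withr::with_seed(seed, {
    kind <- sample(c("missense", "nonsense", "splice"), n, replace = TRUE,
                   prob = c(0.7, 0.15, 0.15))
    af <- ifelse(runif(n) < 0.15, 0, 10^runif(n, -6, -1.5))
    af[runif(n) < 0.1] <- NA
    tools <- prediction_tools()
    panel <- lapply(seq_len(nrow(tools)), function(k) {
      x <- runif(n, tools$lower[k], tools$upper[k])
      x[runif(n) < 0.2] <- NA
      x
    })
    names(panel) <- tools$tool
    df <- tibble::tibble(
      gene = sample(c("G1", "G2"), n, replace = TRUE),
      cdna = sprintf("%dA>T", seq_len(n)),
      protein = ifelse(kind == "splice", NA,
                       ifelse(kind == "nonsense", "W10*", "A10V")),
      af = af,
      splice_likelihood = ifelse(kind == "splice", runif(n, 0, 100), NA),
      inheritance = sample(c("de_novo", "inherited", "unknown"), n, replace = TRUE),
      cohort = "case",
      case_id = sprintf("R%04d", seq_len(n))
    )
    for (tl in names(panel)) df[[tl]] <- panel[[tl]]
    df$kind <- kind
    df$ref_aa <- ifelse(kind == "splice", NA, ifelse(kind == "nonsense", "W", "A"))
    df$position <- ifelse(kind == "splice", NA_integer_, 10L)
    df$alt_aa <- ifelse(kind == "splice", NA, ifelse(kind == "nonsense", "*", "V"))
    df
  })
}

acmg_rank <- function(cls) {
  unname(c(B = 1, LB = 2, VUS = 3, LP = 4, P = 5)[cls])
}
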