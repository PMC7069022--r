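toy_logcpm <- function(values, sample_prefix = "s") {
  # values: genes x samples numeric matrix on the log scale
  colnames(values) <- paste0(sample_prefix, seq_len(ncol(values)))
  rownames(values) <- paste0("g", seq_len(nrow(values)))
  df <- tibble::as_tibble(as.data.frame(values))
  df <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(values)), df)
  expression_matrix(df, unit = "normalized_intensity")
}

test_that("log-CPM follows the offset closed form and is scale invariant", {
  x <- expression_matrix(tibble::tibble(gene_id = "g1", s1 = 0), unit = "raw_counts")
  # count 0 with library size 1e6 - 1: log2((0 + 0.5) / 1e6 * 1e6) = log2(0.5)
  x2 <- expression_matrix(tibble::tibble(gene_id = c("g1", "g2"),
                                         s1 = c(0, 1e6 - 1)),
                          unit = "raw_counts")
  lc <- log_cpm(x2)
  expect_equal(lc$s1[1], log2(0.5))

  # proportional columns give equal per-gene log-CPM (up to the small +0.5
  # count and +1 library offsets, negligible at realistic depth)
  y <- expression_matrix(tibble::tibble(gene_id = c("a", "b", "c"),
                                        s1 = c(10, 20, 70) * 1e3,
                                        s2 = c(20, 40, 140) * 1e3),
                         unit = "raw_counts")
  ly <- log_cpm(y)
  expect_equal(ly$s1, ly$s2, tolerance = 1e-4)

  # doubling one count at (essentially) fixed library size raises its
  # log-CPM by less than 1, approaching 1 as the count grows
  base <- 1e6
  lcpm <- function(k) log2((k + 0.5) / (base + 1) * 1e6)
  gain_small <- lcpm(2) - lcpm(1)
  gain_large <- lcpm(2e5) - lcpm(1e5)
  expect_lt(gain_small, 1)
  expect_gt(gain_large, 0.99)
  expect_lt(gain_large, 1)

  expect_error(log_cpm(expression_matrix(tibble::tibble(gene_id = "g", s1 = 1),
                                         unit = "fpkm")),
               class = "mycnfunnel_data_error")
  zero <- expression_matrix(tibble::tibble(gene_id = "g", s1 = 0, s2 = 1),
                            unit = "raw_counts")
  expect_error(log_cpm(zero), "s1", class = "mycnfunnel_data_error")
})

test_that("precision weights track the planted mean-variance relation", {
  labels <- rep(c("high", "low"), each = 15)
  withr::with_seed(42, {
    # homoscedastic: constant sd regardless of mean -> near-constant weights
    mu <- runif(2000, 2, 12)
    y <- matrix(rnorm(2000 * 30, mean = mu, sd = 0.5), 2000, 30)
    w <- fit_voom_weights(toy_logcpm(y), labels)
    expect_lt(stats::sd(w) / mean(w), 0.2)

    # decreasing sd with mean -> weights increase with mean
    sdv <- 1.2 - 0.08 * mu
    y2 <- matrix(rnorm(2000 * 30, mean = mu, sd = sdv), 2000, 30)
    w2 <- fit_voom_weights(toy_logcpm(y2), labels)
    expect_gt(stats::cor(mu, rowMeans(w2), method = "spearman"), 0.8)
  })
})

test_that("degenerate zero-variance genes get finite weights", {
  y <- matrix(rep(c(1, 2, 3, 4), each = 6), nrow = 4, byrow = TRUE)
  w <- fit_voom_weights(toy_logcpm(y), rep(c("high", "low"), each = 3))
  expect_true(all(is.finite(w)))
  expect_true(all(w > 0))
})

test_that("moderated t is null at equal group means and antisymmetric", {
  y <- matrix(c(5, 5, 5, 5,
                2, 2, 2, 2,
                1, 3, 1, 3), nrow = 3, byrow = TRUE)
  lab <- c("high", "high", "low", "low")
  res <- moderated_t_test(toy_logcpm(y), lab)
  expect_equal(res$log_fc[1:2], c(0, 0))
  expect_equal(res$moderated_t[1:2], c(0, 0))
  expect_equal(res$raw_p[1:2], c(1, 1))

  swapped <- moderated_t_test(toy_logcpm(y), c("low", "low", "high", "high"))
  expect_equal(swapped$log_fc, -res$log_fc)
  expect_equal(swapped$moderated_t, -res$moderated_t)
  expect_equal(swapped$raw_p, res$raw_p)
})

test_that("forced prior limits match the direct formulas on a toy matrix", {
  withr::with_seed(7, {
    y <- matrix(rnorm(5 * 10), 5, 10)
  })
  lab <- rep(c("high", "low"), each = 5)
  lc <- toy_logcpm(y)

  # direct per-gene quantities
  hi <- 1:5; lo <- 6:10
  m_h <- rowMeans(y[, hi]); m_l <- rowMeans(y[, lo])
  rss <- rowSums((y[, hi] - m_h)^2) + rowSums((y[, lo] - m_l)^2)
  s2 <- rss / 8
  sdu <- sqrt(1 / 5 + 1 / 5)

  # d0 = 0: ordinary (unmoderated) t on n - 2 df
  r0 <- moderated_t_test(lc, lab, prior_df = 0)
  t0 <- (m_h - m_l) / (sqrt(s2) * sdu)
  expect_equal(r0$moderated_t, unname(t0))
  expect_equal(r0$raw_p, unname(2 * pt(-abs(t0), df = 8)))

  # d0 = Inf: z-like statistic with the pooled common variance
  rInf <- moderated_t_test(lc, lab, prior_df = Inf)
  tInf <- (m_h - m_l) / (sqrt(mean(s2)) * sdu)
  expect_equal(rInf$moderated_t, unname(tInf))
  expect_equal(rInf$raw_p, unname(2 * stats::pnorm(-abs(tInf))))
})

test_that("the weighted moderated pipeline reproduces the reference implementation", {
  skip_if_not_installed("limma")
  co <- simulate_cohort(n_genes = 600, n_samples = 24, amplified_fraction = 0.5,
                        n_target_genes = 30, seed = 11)
  groups <- stratify(co$expression, co$annotation, mode = "by_status")
  lab <- stats::setNames(groups$group_label, groups$sample_id)
  lc <- log_cpm(co$expression)
  w <- fit_voom_weights(lc, lab)
  mine <- moderated_t_test(lc, lab, weights = w)

  m <- as.matrix(co$expression[, -1])
  rownames(m) <- co$expression$gene_id
  design <- stats::model.matrix(~ factor(lab, levels = c("low", "high")))
  v <- limma::voom(m, design)
  fit <- limma::eBayes(limma::lmFit(v, design))
  ref <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")

  expect_equal(mine$log_fc, unname(ref$logFC), tolerance = 1e-10)
  expect_equal(mine$moderated_t, unname(ref$t), tolerance = 1e-8)
  expect_equal(mine$raw_p, unname(ref$P.Value), tolerance = 1e-8)
  expect_equal(attr(mine, "df_prior"), unname(fit$df.prior), tolerance = 1e-6)
  expect_equal(w, v$weights, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("Benjamini-Hochberg matches the step-up formula and input order", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_hochberg(0.03), 0.03)
  p <- c(0.04, 0.001, 0.2, 0.03, 0.8)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(benjamini_hochberg(p)[perm], benjamini_hochberg(p[perm]))
  expect_true(all(benjamini_hochberg(p) >= p))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), class = "mycnfunnel_data_error")
})

test_that("stratification modes assign groups deterministically", {
  counts <- withr::with_seed(30, {
    m <- matrix(rpois(5 * 20, 50), 5, 20)
    m[1, ] <- seq(10, 200, by = 10)  # driver expression, strictly increasing
    m
  })
  colnames(counts) <- sprintf("s%02d", 1:20)
  x <- expression_matrix(
    dplyr::bind_cols(tibble::tibble(gene_id = c("MYCN", paste0("g", 1:4))),
                     tibble::as_tibble(as.data.frame(counts))),
    unit = "raw_counts"
  )
  ann <- tibble::tibble(sample_id = colnames(counts),
                        mycn_status = rep(c("amplified", "non_amplified"), 10))

  q <- stratify(x, ann, mode = "by_quantile", driver_gene_id = "MYCN",
                quantile_fraction = 0.15)
  expect_identical(sum(q$group_label == "high"), 3L)   # floor(0.15 * 20) = 3
  expect_identical(sum(q$group_label == "low"), 3L)
  expect_identical(sum(q$group_label == "excluded"), 14L)
  expect_setequal(q$sample_id[q$group_label == "high"], c("s18", "s19", "s20"))

  # permuting sample order leaves the assignment unchanged
  perm <- withr::with_seed(1, sample(20))
  q2 <- stratify(x, ann[perm, ], mode = "by_quantile", driver_gene_id = "MYCN",
                 quantile_fraction = 0.15)
  merged <- dplyr::inner_join(q, q2, by = "sample_id")
  expect_identical(merged$group_label.x, merged$group_label.y)

  # full ties: the ascending (expression, sample id) ordering keeps the two
  # tails disjoint and deterministic
  xt <- x
  xt[xt$gene_id == "MYCN", -1] <- as.list(rep(5, 20))
  qt <- stratify(xt, ann, mode = "by_quantile", driver_gene_id = "MYCN",
                 quantile_fraction = 0.15)
  expect_setequal(qt$sample_id[qt$group_label == "low"], c("s01", "s02", "s03"))
  expect_setequal(qt$sample_id[qt$group_label == "high"], c("s18", "s19", "s20"))

  s <- stratify(x, ann, mode = "by_status")
  expect_identical(s$group_label[s$mycn_status == "amplified"],
                   rep("high", 10))
  all_amp <- dplyr::mutate(ann, mycn_status = "amplified")
  expect_error(stratify(x, all_amp, mode = "by_status"),
               class = "mycnfunnel_config_error")
  unk <- dplyr::mutate(ann, mycn_status = replace(mycn_status, 1, "unknown"))
  expect_error(stratify(x, unk, mode = "by_status"),
               class = "mycnfunnel_config_error")
  expect_error(stratify(x, ann, mode = "by_quantile", driver_gene_id = "nope"),
               class = "mycnfunnel_config_error")
  expect_error(stratify(x, ann[1:3, ], mode = "by_quantile",
                        quantile_fraction = 0.5),
               class = "mycnfunnel_config_error")
})

test_that("the screen recovers planted targets with few false discoveries", {
  sens <- c(); fdp <- c()
  for (seed in 1:3) {
    co <- simulate_cohort(n_genes = 1000, n_samples = 60,
                          amplified_fraction = 0.5, n_target_genes = 40,
                          target_log2fc = 1.5, seed = seed)
    groups <- stratify(co$expression, co$annotation, mode = "by_status")
    scr <- differential_screen(co$expression, groups)
    truth <- c(co$truth, co$driver_gene_id)
    sens <- c(sens, mean(co$truth %in% scr$survivors))
    fdp <- c(fdp, if (length(scr$survivors) > 0) {
      mean(!(scr$survivors %in% truth))
    } else 0)
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdp), 0.1)
})

test_that("both platform screens contain the strong truth genes", {
  co <- simulate_cohort(n_genes = 800, n_samples = 60, amplified_fraction = 0.5,
                        n_target_genes = 25, target_log2fc = 2.5, seed = 19)
  groups <- stratify(co$expression, co$annotation, mode = "by_status")
  scr_rna <- differential_screen(co$expression, groups)
  intens <- log_cpm(co$expression)
  groups_q <- stratify(intens, co$annotation, mode = "by_quantile",
                       driver_gene_id = co$driver_gene_id)
  scr_arr <- differential_screen(intens, groups_q)
  both <- intersect(scr_rna$survivors, scr_arr$survivors)
  expect_true(all(co$truth %in% both))
})
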