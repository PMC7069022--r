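test_that("candidate assembly intersects both platforms and the membrane list", {
  de_rna <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                           log_fc = c(2, 2, 2),
                           adj_p = c(1e-4, 1e-4, 1e-4))
  de_arr <- tibble::tibble(gene_id = c("g1", "g3"),
                           log_fc = c(1.5, 1.5),
                           adj_p = c(1e-3, 1e-3))
  verdicts <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                             membrane = c(TRUE, TRUE, FALSE),
                             limited_normal_expression = TRUE,
                             not_secreted = TRUE)
  rows <- assemble_candidates(de_rna, de_arr, verdicts,
                              motif_genes = "g1", occupancy = NULL)
  # g2 passes RNA-seq only; g3 fails the membrane list
  expect_identical(rows$gene_id, "g1")
  expect_true(rows$ebox_near_tss)
  expect_false(rows$mycn_bound_near_tss)  # empty occupancy -> flags false
  expect_false(rows$ebox_occupied)

  # a missing array log-FC passes on its adjusted p alone
  de_arr_na <- tibble::tibble(gene_id = c("g1", "g2"),
                              log_fc = c(1.5, NA),
                              adj_p = c(1e-3, 1e-3))
  rows2 <- assemble_candidates(de_rna, de_arr_na, verdicts,
                               motif_genes = character(0), occupancy = NULL)
  expect_setequal(rows2$gene_id, c("g1", "g2"))
  expect_true(is.na(rows2$array_log_fc[rows2$gene_id == "g2"]))

  dup <- dplyr::bind_rows(de_rna, de_rna[1, ])
  expect_error(assemble_candidates(dup, de_arr, verdicts, "g1"),
               class = "mycnfunnel_data_error")
})

test_that("the bundled candidate matrix reassembles from its column values", {
  fx <- nb_candidate_matrix()
  de_rna <- tibble::tibble(gene_id = fx$gene_id, log_fc = fx$rnaseq_log_fc,
                           adj_p = fx$rnaseq_adj_p, pass = TRUE)
  de_arr <- tibble::tibble(gene_id = fx$gene_id, log_fc = fx$array_log_fc,
                           adj_p = fx$array_adj_p, pass = TRUE)
  verdicts <- tibble::tibble(gene_id = fx$gene_id, membrane = TRUE,
                             limited_normal_expression = fx$limited_normal_expression,
                             not_secreted = fx$not_secreted)
  occ <- tibble::tibble(gene_id = fx$gene_id,
                        mycn_bound_near_tss = fx$mycn_bound_near_tss,
                        ebox_occupied = fx$ebox_occupied)
  rows <- assemble_candidates(de_rna, de_arr, verdicts,
                              motif_genes = fx$gene_id[fx$ebox_near_tss],
                              occupancy = occ)
  expect_identical(rows[order(rows$gene_id), names(fx)],
                   fx[order(fx$gene_id), ])
})

test_that("funnel attrition on toy matrices is forced by the flags", {
  all_true <- tibble::tibble(
    gene_id = sprintf("g%d", 1:5),
    rnaseq_log_fc = 2, rnaseq_adj_p = 1e-5,
    ebox_near_tss = TRUE, mycn_bound_near_tss = TRUE, ebox_occupied = TRUE,
    limited_normal_expression = TRUE, not_secreted = TRUE
  )
  expect_identical(tidy(apply_funnel(all_true))$n_survivors, rep(5L, 6))

  one <- dplyr::mutate(all_true[1, ], ebox_near_tss = FALSE,
                       mycn_bound_near_tss = FALSE, ebox_occupied = FALSE)
  expect_identical(tidy(apply_funnel(one))$n_survivors,
                   c(1L, 0L, 0L, 0L, 0L, 0L))

  bad <- dplyr::mutate(all_true, mycn_bound_near_tss = FALSE)
  expect_error(apply_funnel(bad), "implies", class = "mycnfunnel_data_error")
  na_flag <- dplyr::mutate(all_true, not_secreted = NA)
  expect_error(apply_funnel(na_flag), class = "mycnfunnel_data_error")
})

test_that("survivor sets are nested and match brute-force conjunction counts", {
  flags <- c("ebox_near_tss", "mycn_bound_near_tss", "ebox_occupied",
             "limited_normal_expression", "not_secreted")
  for (seed in 1:10) {
    rows <- random_candidate_rows(40, seed = seed)
    fr <- apply_funnel(rows)
    sets <- fr$stages$survivors
    for (i in 2:length(sets)) {
      expect_true(all(sets[[i]] %in% sets[[i - 1]]))
    }
    # oracle: count rows satisfying the conjunction of flags up to stage k
    for (k in seq_along(flags)) {
      keep <- rep(TRUE, nrow(rows))
      for (f in flags[seq_len(k)]) keep <- keep & rows[[f]]
      expect_identical(fr$stages$n_survivors[k + 1], sum(keep))
    }
    # conjunctive stages: the final set equals the flag conjunction evaluated
    # in any order (AND is commutative)
    for (ord in list(flags, rev(flags), flags[c(3, 1, 5, 2, 4)])) {
      keep <- rep(TRUE, nrow(rows))
      for (f in ord) keep <- keep & rows[[f]]
      expect_setequal(fr$stages$survivors[[6]], rows$gene_id[keep])
    }
  }
})

test_that("ranking keys and tie-breaks are deterministic and documented", {
  fx <- nb_candidate_matrix()
  rep_p <- apply_funnel(fx, rank_by = "adj_p")
  # by adjusted p the published table ranks NME1 (1.17e-6) ahead of CAMKV
  expect_identical(rep_p$final_ranked$gene_id, c("NME1", "CAMKV"))
  rep_fc <- apply_funnel(fx, rank_by = "log_fc")
  expect_identical(rep_fc$final_ranked$gene_id, c("CAMKV", "NME1"))

  single <- rank_candidates(fx, "CAMKV")
  expect_identical(single$gene_id, "CAMKV")

  twin <- tibble::tibble(gene_id = c("zz", "aa"),
                         rnaseq_adj_p = 1e-6, rnaseq_log_fc = 2)
  expect_identical(rank_candidates(twin, twin$gene_id)$gene_id, c("aa", "zz"))
})

test_that("correlation handles identity, negation and simulated dependence", {
  x <- expression_matrix(
    tibble::tibble(gene_id = c("a", "b", "c"),
                   s1 = c(1, 9, 5), s2 = c(2, 8, 5), s3 = c(5, 5, 5),
                   s4 = c(9, 1, 5)),
    unit = "fpkm"
  )
  expect_equal(correlate(x, "a", "a")$r, 1)
  expect_equal(correlate(x, "a", "b")$r, -1)
  expect_error(correlate(x, "a", "c"), class = "mycnfunnel_data_error")
  expect_error(correlate(x, "a", "zz"), class = "mycnfunnel_data_error")

  rs <- vapply(1:50, function(seed) {
    withr::with_seed(seed, {
      n <- 150
      u <- rnorm(n)
      a <- u + rnorm(n, sd = sqrt(1 / 0.6^2 - 1) * 1)  # corr ~ 0.6 with u
      m <- expression_matrix(
        tibble::tibble(gene_id = c("MYCN", "CAMKV"),
                       !!!stats::setNames(as.list(as.data.frame(rbind(u, a) + 100)),
                                          sprintf("s%03d", 1:n))),
        unit = "fpkm"
      )
      correlate(m, "MYCN", "CAMKV")$r
    })
  }, numeric(1))
  expect_equal(mean(rs), 0.6, tolerance = 0.05)
})

test_that("tidy, glance, autoplot and print cover both result types", {
  fx <- nb_candidate_matrix()
  rep <- apply_funnel(fx)
  expect_identical(tidy(rep)$stage[1], "candidate_matrix")
  gl <- glance(rep)
  expect_identical(gl$n_initial, 14L)
  expect_identical(gl$n_final, 2L)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_output(print(rep), "not_secreted")

  co <- simulate_cohort(n_genes = 200, n_samples = 20, amplified_fraction = 0.5,
                        n_target_genes = 10, seed = 77)
  scr <- differential_screen(co$expression,
                             stratify(co$expression, co$annotation, "by_status"))
  expect_true(all(c("gene_id", "log_fc", "adj_p", "pass") %in% names(tidy(scr))))
  expect_true(all(tidy(scr)$adj_p >= tidy(scr)$raw_p))
  expect_s3_class(autoplot(scr), "ggplot")
  expect_output(print(scr), "screen")
})

test_that("the full pipeline recovers the planted candidate set", {
  co <- simulate_cohort(n_genes = 1000, n_samples = 60, amplified_fraction = 0.5,
                        n_target_genes = 40, seed = 301)
  ge <- simulate_genome(gene_ids = co$expression$gene_id,
                        ebox_plant_probability = 0.6, seed = 302)
  ch <- simulate_chip(ge, amplified_flags = c(k = TRUE, n = TRUE, g = TRUE),
                      peak_q_at_planted_sites = 0.001, decoy_peak_rate = 0,
                      seed = 303)
  an <- simulate_annotations(co$expression$gene_id, membrane_fraction = 0.6,
                             cns_only_fraction = 0.5, secreted_fraction = 0.1,
                             seed = 304)
  res <- run_funnel_pipeline(co$expression, co$annotation,
                             genes = ge$genes, promoters = ge$promoters,
                             peaks_by_line = ch,
                             localization = an$localization,
                             tissues = an$tissues,
                             cns_tissues = an$cns_tissues)
  truth_de <- c(co$truth, co$driver_gene_id)
  truth_full <- intersect(
    intersect(truth_de, ge$truth),
    an$truth$gene_id[an$truth$membrane & an$truth$cns_only & !an$truth$secreted]
  )
  final <- res$report$final_ranked$gene_id
  expect_gte(mean(truth_full %in% final), 0.9)
  if (length(final) > 0) {
    expect_lte(mean(!(final %in% truth_full)), 0.1)
  }
  # counts are non-increasing down the funnel
  expect_true(all(diff(tidy(res$report)$n_survivors) <= 0))
})
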