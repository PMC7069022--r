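# Simulators for every input the funnel consumes: a tumor cohort with an
# amplified subgroup, a toy genome of promoters with planted E-boxes, ChIP
# peak sets concentrated at those E-boxes in amplified cell lines, and
# localization / normal-tissue annotation tables. All are fully deterministic
# under `seed` and return the planted truth alongside the data so recovery can
# be scored.

#' Simulate a tumor cohort with an amplified subgroup
#'
#' Counts are drawn from a negative-binomial model parameterised by mean and
#' dispersion (variance = mu + dispersion * mu^2), the standard desk-scale
#' surrogate for RNA-seq expected counts. Per-gene baseline means are
#' log-normal around `baseline_mean`. In amplified samples the driver gene's
#' mean is shifted by `2^driver_log2fc` and each planted target gene's mean by
#' `2^target_log2fc`; all other genes are null.
#'
#' @param n_genes,n_samples Cohort dimensions.
#' @param amplified_fraction Fraction of samples carrying the amplification;
#'   must leave at least 2 samples in each group.
#' @param driver_gene_id Identifier given to the driver gene (first row).
#' @param n_target_genes Number of driver-responsive target genes to plant.
#' @param target_log2fc Planted log2 fold change of target genes in amplified
#'   samples (default 1.5, chosen to straddle a screen threshold of 1).
#' @param driver_log2fc Planted log2 fold change of the driver itself
#'   (default 3, large so that status-based and expression-quantile
#'   stratification select concordant groups).
#' @param nb_dispersion Negative-binomial dispersion (> 0).
#' @param baseline_mean Median of the per-gene baseline mean distribution.
#' @param seed Integer RNG seed; identical seeds give byte-identical output.
#' @return A list with `expression` (an [expression_matrix()] of raw counts),
#'   `annotation` (tibble: `sample_id`, `mycn_status`), `truth` (character
#'   vector of planted target gene ids, excluding the driver) and
#'   `driver_gene_id`.
#' @export
simulate_cohort <- function(n_genes = 2000, n_samples = 60,
                            amplified_fraction = 0.4,
                            driver_gene_id = "MYCN",
                            n_target_genes = 50,
                            target_log2fc = 1.5,
                            driver_log2fc = 3,
                            nb_dispersion = 0.1,
                            baseline_mean = 100,
                            seed) {
  if (n_target_genes >= n_genes) {
    abort_config("`n_target_genes` must be smaller than `n_genes`.")
  }
  check_fraction(amplified_fraction, "amplified_fraction")
  if (nb_dispersion <= 0) abort_config("`nb_dispersion` must be > 0.")
  if (baseline_mean <= 0) abort_config("`baseline_mean` must be > 0.")
  n_amp <- round(amplified_fraction * n_samples)
  if (n_amp < 2 || n_samples - n_amp < 2) {
    abort_config("`amplified_fraction` must yield at least 2 samples per group.")
  }
  with_seed(seed, {
    gene_ids <- c(driver_gene_id, sprintf("G%05d", seq_len(n_genes - 1)))
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    status <- c(rep("amplified", n_amp), rep("non_amplified", n_samples - n_amp))
    truth <- sort(sample(gene_ids[-1], n_target_genes))
    base_mu <- stats::rlnorm(n_genes, meanlog = log(baseline_mean), sdlog = 1)
    names(base_mu) <- gene_ids
    fc <- rep(1, n_genes)
    names(fc) <- gene_ids
    fc[driver_gene_id] <- 2^driver_log2fc
    fc[truth] <- 2^target_log2fc
    counts <- matrix(0, n_genes, n_samples, dimnames = list(gene_ids, sample_ids))
    for (j in seq_len(n_samples)) {
      mu_j <- if (status[j] == "amplified") base_mu * fc else base_mu
      counts[, j] <- stats::rnbinom(n_genes, mu = mu_j, size = 1 / nb_dispersion)
    }
    list(
      expression = expr_from_matrix(counts, unit = "raw_counts"),
      annotation = tibble(sample_id = sample_ids, mycn_status = status),
      truth = truth,
      driver_gene_id = driver_gene_id
    )
  })
}

#' Simulate a toy genome of promoter regions
#'
#' Lays genes along one synthetic chromosome with non-overlapping promoter
#' windows, draws random promoter sequences with a configurable GC content,
#' and plants one exact CACGTG E-box at a random recorded offset in a random
#' subset of promoters. Promoter sequences are emitted strand-oriented (5' to
#' 3' along the gene), so for minus-strand genes the stored sequence is the
#' reverse complement of the genomic window.
#'
#' @param n_genes Number of genes, or supply `gene_ids` directly.
#' @param gene_ids Optional explicit gene identifiers (e.g. from
#'   [simulate_cohort()]) so genomes align with cohorts.
#' @param promoter_len Total promoter window length in bp (>= 6). The window
#'   spans `upstream = floor(promoter_len/2)` bp upstream and
#'   `promoter_len - upstream` bp downstream of the TSS.
#' @param ebox_plant_probability Per-gene probability of planting a CACGTG.
#' @param background_gc Background GC fraction of the random sequence.
#' @param spacer_bp Gap between consecutive promoter windows.
#' @param chrom Name of the synthetic chromosome.
#' @param seed Integer RNG seed.
#' @return A list with `genes` (tibble: `gene_id`, `chrom`, `tss` 0-based,
#'   `strand`), `promoters` (named [Biostrings::DNAStringSet]), `truth`
#'   (character vector of gene ids with a planted E-box), `planted` (tibble:
#'   `gene_id`, `start_in_promoter` 0-based, plus genomic `chrom`, `start`,
#'   `end` of the planted motif), and the window geometry `upstream`,
#'   `downstream`, `chrom_length`.
#' @export
simulate_genome <- function(n_genes = 2000, gene_ids = NULL,
                            promoter_len = 2000,
                            ebox_plant_probability = 0.3,
                            background_gc = 0.4,
                            spacer_bp = 1000,
                            chrom = "chrS",
                            seed) {
  if (is.null(gene_ids)) gene_ids <- sprintf("G%05d", seq_len(n_genes))
  n_genes <- length(gene_ids)
  if (promoter_len < 6) abort_config("`promoter_len` must be at least 6 (the motif width).")
  check_fraction(ebox_plant_probability, "ebox_plant_probability")
  check_fraction(background_gc, "background_gc", lo = 0, hi = 1)
  upstream <- promoter_len %/% 2
  downstream <- promoter_len - upstream
  with_seed(seed, {
    spacing <- promoter_len + spacer_bp
    tss <- upstream + spacer_bp + (seq_len(n_genes) - 1L) * spacing
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    genes <- tibble(gene_id = gene_ids, chrom = chrom, tss = as.integer(tss),
                    strand = strand)
    p <- c((1 - background_gc) / 2, background_gc / 2, background_gc / 2,
           (1 - background_gc) / 2)
    seqs <- vapply(seq_len(n_genes), function(i) {
      paste(sample(c("A", "C", "G", "T"), promoter_len, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    planted_flag <- runif(n_genes) < ebox_plant_probability
    offs <- rep(NA_integer_, n_genes)
    for (i in which(planted_flag)) {
      o <- sample.int(promoter_len - 6L + 1L, 1L) - 1L
      substr(seqs[i], o + 1L, o + 6L) <- "CACGTG"
      offs[i] <- o
    }
    names(seqs) <- gene_ids
    windows <- promoter_windows(genes, upstream = upstream, downstream = downstream)
    planted <- tibble(gene_id = gene_ids, start_in_promoter = offs)[planted_flag, ]
    planted <- left_join(planted, windows, by = "gene_id")
    planted <- mutate(planted,
      start = ifelse(.data$strand == "+",
                     .data$win_start + .data$start_in_promoter,
                     .data$win_end - .data$start_in_promoter - 6L),
      end = .data$start + 6L
    )
    planted <- select(planted, "gene_id", "start_in_promoter", "chrom", "start", "end")
    list(
      genes = genes,
      promoters = Biostrings::DNAStringSet(seqs),
      truth = gene_ids[planted_flag],
      planted = planted,
      upstream = upstream,
      downstream = downstream,
      chrom_length = as.integer(max(tss) + promoter_len + spacer_bp)
    )
  })
}

#' Simulate ChIP-seq peak sets over a simulated genome
#'
#' Amplified cell lines receive one peak centred on every planted E-box, with
#' the configured q-value; every line additionally receives decoy peaks at
#' uniform random positions. Non-amplified lines receive only decoys,
#' emulating the absence of driver occupancy.
#'
#' @param genome Output of [simulate_genome()].
#' @param amplified_flags Named (or unnamed) logical vector, one per cell
#'   line; names become cell-line identifiers (default `CL1`, `CL2`, ...).
#' @param peak_q_at_planted_sites q-value assigned to peaks at planted
#'   E-boxes, in (0, 1).
#' @param decoy_peak_rate Expected number of decoy peaks per gene (Poisson).
#' @param peak_halfwidth Half-width in bp of planted-site peaks.
#' @param seed Integer RNG seed.
#' @return A named list, one peak tibble (narrowPeak-shaped, as from
#'   [read_narrowpeak()]) per cell line.
#' @export
simulate_chip <- function(genome,
                          amplified_flags = c(TRUE, TRUE, TRUE),
                          peak_q_at_planted_sites = 0.001,
                          decoy_peak_rate = 0.1,
                          peak_halfwidth = 75,
                          seed) {
  if (!is.logical(amplified_flags) || anyNA(amplified_flags)) {
    abort_config("`amplified_flags` must be a logical vector without missing values.")
  }
  check_fraction(peak_q_at_planted_sites, "peak_q_at_planted_sites")
  if (peak_q_at_planted_sites <= 0 || peak_q_at_planted_sites >= 1) {
    abort_config("`peak_q_at_planted_sites` must lie strictly in (0, 1).")
  }
  if (decoy_peak_rate < 0) abort_config("`decoy_peak_rate` must be >= 0.")
  lines <- names(amplified_flags) %||% sprintf("CL%d", seq_along(amplified_flags))
  if (is.null(names(amplified_flags))) names(amplified_flags) <- lines
  n_genes <- nrow(genome$genes)
  chrom <- genome$genes$chrom[1]
  with_seed(seed, {
    out <- lapply(lines, function(cl) {
      peaks <- empty_peaks()
      if (amplified_flags[[cl]] && nrow(genome$planted) > 0) {
        centre <- (genome$planted$start + genome$planted$end) %/% 2L
        peaks <- tibble(
          chrom = chrom,
          start = pmax(0L, as.integer(centre - peak_halfwidth)),
          end = as.integer(centre + peak_halfwidth),
          name = sprintf("%s_planted_%s", cl, genome$planted$gene_id),
          score = 0,
          strand = ".",
          signal = round(runif(nrow(genome$planted), 5, 50), 3),
          p_log10 = -log10(peak_q_at_planted_sites) + 1,
          q_value = peak_q_at_planted_sites,
          summit_offset = as.integer(peak_halfwidth)
        )
      }
      n_decoy <- rpois(1, decoy_peak_rate * n_genes)
      if (n_decoy > 0) {
        width <- 2L * as.integer(peak_halfwidth)
        start <- as.integer(floor(runif(n_decoy, 0, genome$chrom_length - width)))
        decoys <- tibble(
          chrom = chrom,
          start = start,
          end = start + width,
          name = sprintf("%s_decoy_%d", cl, seq_len(n_decoy)),
          score = 0,
          strand = ".",
          signal = round(runif(n_decoy, 1, 10), 3),
          p_log10 = 2,
          q_value = runif(n_decoy, 0.001, 0.049),
          summit_offset = NA_integer_
        )
        peaks <- bind_rows(peaks, decoys)
      }
      arrange(peaks, .data$start)
    })
    names(out) <- lines
    out
  })
}

#' Simulate localization and normal-tissue annotation tables
#'
#' Emulates, schema-compatibly, a subcellular-localization confidence table
#' (per-gene, per-GO-category integer scores 0-5 plus a secreted flag) and a
#' normal-tissue expression table with a declared CNS subset. Genes planted as
#' membrane get their maximal score (>= 3) on "Plasma membrane" or "Cell
#' surface"; genes planted as CNS-restricted exceed the expression threshold
#' only in CNS tissues.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param membrane_fraction,cns_only_fraction,secreted_fraction Independent
#'   per-gene planting probabilities, each in \[0, 1\].
#' @param expr_threshold Normal-tissue expression threshold the planted
#'   CNS-restricted genes stay under outside the CNS (TPM-like units).
#' @param seed Integer RNG seed.
#' @return A list with `localization` (long tibble: `gene_id`, `category`,
#'   `score`, `secreted`), `tissues` (wide tibble: `gene_id` x tissue),
#'   `cns_tissues` (character vector naming the CNS columns) and `truth`
#'   (tibble of the planted per-gene flags `membrane`, `cns_only`,
#'   `secreted`).
#' @export
simulate_annotations <- function(gene_ids,
                                 membrane_fraction = 0.5,
                                 cns_only_fraction = 0.3,
                                 secreted_fraction = 0.2,
                                 expr_threshold = 1,
                                 seed) {
  check_fraction(membrane_fraction, "membrane_fraction")
  check_fraction(cns_only_fraction, "cns_only_fraction")
  check_fraction(secreted_fraction, "secreted_fraction")
  n <- length(gene_ids)
  cns <- c("brain_cortex", "cerebellum", "spinal_cord")
  other <- c("liver", "lung", "heart", "kidney", "whole_blood")
  membrane_cats <- c("Plasma membrane", "Cell surface")
  other_cats <- c("Nucleus", "Cytosol", "Mitochondrion", "Endoplasmic reticulum")
  with_seed(seed, {
    membrane <- runif(n) < membrane_fraction
    cns_only <- runif(n) < cns_only_fraction
    secreted <- runif(n) < secreted_fraction
    loc <- map_dfr(seq_len(n), function(i) {
      if (membrane[i]) {
        top_cat <- sample(membrane_cats, 1)
        top_score <- sample(3:5, 1)
        side_cat <- sample(other_cats, 1)
        side_score <- sample.int(top_score, 1) - 1L
      } else {
        top_cat <- sample(other_cats, 1)
        top_score <- sample(3:5, 1)
        side_cat <- sample(membrane_cats, 1)
        side_score <- sample.int(3, 1) - 1L  # membrane score capped below 3
      }
      tibble(
        gene_id = gene_ids[i],
        category = c(top_cat, side_cat),
        score = as.integer(c(top_score, side_score)),
        secreted = secreted[i]
      )
    })
    tissues <- tibble(gene_id = gene_ids)
    for (tt in cns) {
      tissues[[tt]] <- round(runif(n, expr_threshold * 2, expr_threshold * 50), 3)
    }
    for (tt in other) {
      v <- ifelse(cns_only,
                  runif(n, 0, expr_threshold * 0.5),
                  runif(n, expr_threshold * 2, expr_threshold * 20))
      tissues[[tt]] <- round(v, 3)
    }
    list(
      localization = loc,
      tissues = tissues,
      cns_tissues = cns,
      truth = tibble(gene_id = gene_ids, membrane = membrane,
                     cns_only = cns_only, secreted = secreted)
    )
  })
}
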