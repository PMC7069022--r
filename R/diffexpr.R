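# Stratified differential-expression screen: log-CPM transformation,
# mean-variance precision weights, weighted two-group fits with
# empirical-Bayes variance moderation, Benjamini-Hochberg adjustment, and the
# two stratification modes (amplification status; top/bottom driver-expression
# quantiles).

#' Transform raw counts to log2 counts-per-million
#'
#' `value(g, s) = log2((count + 0.5) / (library_size + 1) * 1e6)`, the
#' standard offset convention for precision-weighted linear modelling of
#' counts. Library sizes are recorded on the result (as attribute
#' `lib_size`) so the weight fit can work on the log-count scale.
#'
#' @param x An [expression_matrix()] with unit `raw_counts`.
#' @return An expression matrix with unit `normalized_intensity`.
#' @export
log_cpm <- function(x) {
  if (!identical(expr_unit(x), "raw_counts")) {
    abort_data(sprintf("log_cpm() requires raw counts; unit is '%s'.", expr_unit(x)))
  }
  m <- expr_values(x)
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort_data(sprintf("Sample '%s' has zero library size.",
                       expr_samples(x)[which(lib == 0)[1]]))
  }
  out <- log2(t((t(m) + 0.5) / (lib + 1)) * 1e6)
  expr_from_matrix(out, unit = "normalized_intensity", lib_size = lib)
}

# Internal: per-gene weighted two-group statistics used by both the weight
# fit and the moderated test. Returns group means, residual sigma and df.
group_fit <- function(y, w, hi, lo) {
  wh <- w[, hi, drop = FALSE]; wl <- w[, lo, drop = FALSE]
  yh <- y[, hi, drop = FALSE]; yl <- y[, lo, drop = FALSE]
  sw_h <- rowSums(wh); sw_l <- rowSums(wl)
  m_h <- rowSums(wh * yh) / sw_h
  m_l <- rowSums(wl * yl) / sw_l
  fitted <- y
  fitted[, hi] <- m_h
  fitted[, lo] <- m_l
  rss <- rowSums(w * (y - fitted)^2)
  df <- ncol(y) - 2L
  list(m_h = m_h, m_l = m_l, sw_h = sw_h, sw_l = sw_l,
       fitted = fitted, s2 = rss / df, df = df)
}

resolve_groups <- function(samples, group_labels) {
  if (!is.null(names(group_labels))) group_labels <- group_labels[samples]
  group_labels <- as.character(group_labels)
  if (length(group_labels) != length(samples)) {
    abort_config("`group_labels` must supply one label per sample column.")
  }
  hi <- which(group_labels == "high")
  lo <- which(group_labels == "low")
  if (length(hi) < 2 || length(lo) < 2) {
    abort_config("Each of the 'high' and 'low' groups needs at least 2 samples.")
  }
  list(hi = hi, lo = lo)
}

#' Fit mean-variance precision weights
#'
#' Fits group means per gene, takes the square root of the residual standard
#' deviation (quarter-root of the variance), smooths it against average log
#' count with `lowess`, and converts the trend back to a per-observation
#' precision weight `w = trend(fitted log-count)^-4`. With count input this
#' is the familiar precision-weighting of log-CPM values; with intensity
#' input (no library sizes) the trend is fit on the log-intensity scale
#' directly.
#'
#' @param logcpm Output of [log_cpm()] (or any expression matrix of
#'   log-intensities).
#' @param group_labels Character vector (one per sample, or named by sample)
#'   with values `"high"` / `"low"`; other labels are ignored upstream.
#' @param span `lowess` smoothing span for the mean-variance trend.
#' @param sd_floor Floor applied to residual standard deviations so
#'   zero-variance genes cannot produce infinite weights.
#' @return Numeric matrix of positive weights, genes x samples.
#' @export
fit_voom_weights <- function(logcpm, group_labels, span = 0.5, sd_floor = 1e-8) {
  y <- expr_values(logcpm)
  g <- resolve_groups(expr_samples(logcpm), group_labels)
  idx <- c(g$hi, g$lo)
  y <- y[, idx, drop = FALSE]
  lib <- attr(logcpm, "lib_size", exact = TRUE)
  if (!is.null(lib)) lib <- lib[idx]
  w1 <- matrix(1, nrow(y), ncol(y))
  fit <- group_fit(y, w1, seq_along(g$hi), seq_along(g$lo) + length(g$hi))
  sdev <- sqrt(pmax(fit$s2, sd_floor^2))
  # Average log-count per gene; without library sizes, average log-intensity.
  if (!is.null(lib)) {
    sx <- rowMeans(y) + mean(log2(lib + 1)) - log2(1e6)
  } else {
    sx <- rowMeans(y)
  }
  sy <- sqrt(sdev)
  l <- stats::lowess(sx, sy, f = span)
  trend <- stats::approxfun(l, rule = 2, ties = mean)
  fitted_logcount <- fit$fitted
  if (!is.null(lib)) {
    fitted_logcount <- t(t(fit$fitted) + log2(lib + 1)) - log2(1e6)
  }
  pred <- trend(as.vector(fitted_logcount))
  pred <- pmax(pred, sqrt(sd_floor))
  w <- matrix(1 / pred^4, nrow(y), ncol(y))
  # restore original column order
  out <- matrix(1, nrow(y), length(expr_samples(logcpm)),
                dimnames = list(rownames(y), expr_samples(logcpm)))
  out[, idx] <- w
  out
}

# Solve trigamma(x) = y by Newton iteration (monotone decreasing, convex).
trigamma_inverse <- function(y) {
  out <- y
  hi <- y > 1e7
  lo <- y < 1e-6
  out[hi] <- 1 / sqrt(y[hi])
  out[lo] <- 1 / y[lo]
  mid <- !hi & !lo
  x <- 0.5 + 1 / y[mid]
  for (i in seq_len(50)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-8) break
  }
  out[mid] <- x
  out
}

# Moment-match a scaled-F prior to the observed residual variances: on the
# log scale, log s^2 - digamma(d/2) + log(d/2) has mean log s0^2 +
# digamma(d0/2) - log(d0/2) and excess variance trigamma(d0/2).
fit_f_dist <- function(s2, df) {
  ok <- s2 > 0 & df > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    s2_prior <- exp(emean)
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

#' Moderated two-group t-test with precision weights
#'
#' Per gene: a weighted two-group linear fit gives the log fold change
#' (high minus low) and a residual variance on `n - 2` degrees of freedom.
#' Residual variances are shrunk towards a common prior whose degrees of
#' freedom `d0` and scale `s0^2` are estimated by moment matching of the
#' scaled-F distribution of the sample variances; the moderated t-statistic
#' uses the shrunken variance and is referred to a t distribution with
#' `(n - 2) + d0` degrees of freedom.
#'
#' @inheritParams fit_voom_weights
#' @param weights Optional precision-weight matrix from
#'   [fit_voom_weights()]; defaults to unit weights.
#' @param prior_df Optional override of the estimated prior degrees of
#'   freedom: `0` gives the ordinary weighted t-test, `Inf` pools to the
#'   common variance. Mainly for verification.
#' @return A tibble with one row per gene: `gene_id`, `log_fc`,
#'   `mean_expression`, `moderated_t`, `raw_p`, `df_total`; the estimated
#'   `df_prior` and `s2_prior` are attached as attributes.
#' @export
moderated_t_test <- function(logcpm, group_labels, weights = NULL,
                             prior_df = NULL) {
  y <- expr_values(logcpm)
  g <- resolve_groups(expr_samples(logcpm), group_labels)
  idx <- c(g$hi, g$lo)
  if (is.null(weights)) {
    w <- matrix(1, nrow(y), length(idx))
  } else {
    w <- weights[, idx, drop = FALSE]
  }
  yy <- y[, idx, drop = FALSE]
  hi <- seq_along(g$hi)
  lo <- seq_along(g$lo) + length(g$hi)
  fit <- group_fit(yy, w, hi, lo)
  log_fc <- fit$m_h - fit$m_l
  stdev_unscaled <- sqrt(1 / fit$sw_h + 1 / fit$sw_l)
  if (is.null(prior_df)) {
    prior <- fit_f_dist(fit$s2, fit$df)
  } else if (is.infinite(prior_df)) {
    prior <- list(df_prior = Inf, s2_prior = mean(fit$s2))
  } else if (prior_df == 0) {
    prior <- list(df_prior = 0, s2_prior = 0)
  } else {
    prior <- list(df_prior = prior_df, s2_prior = fit_f_dist(fit$s2, fit$df)$s2_prior)
  }
  if (is.infinite(prior$df_prior)) {
    s2_post <- rep(prior$s2_prior, length(fit$s2))
  } else {
    s2_post <- (prior$df_prior * prior$s2_prior + fit$df * fit$s2) /
      (prior$df_prior + fit$df)
  }
  se <- stdev_unscaled * sqrt(s2_post)
  t_stat <- ifelse(se > 0, log_fc / se, 0)
  df_total <- fit$df + prior$df_prior
  raw_p <- 2 * pt(-abs(t_stat), df = df_total)
  out <- tibble(
    gene_id = rownames(y),
    log_fc = unname(log_fc),
    mean_expression = unname(rowMeans(yy)),
    moderated_t = unname(t_stat),
    raw_p = unname(raw_p),
    df_total = df_total
  )
  attr(out, "df_prior") <- prior$df_prior
  attr(out, "s2_prior") <- prior$s2_prior
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order. This is
#' a validating front-end over [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort_data("p-values must be numbers in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Stratify samples into high/low driver-expression groups
#'
#' Two modes. `by_status` maps amplified samples to the high group and
#' non-amplified samples to the low group; samples of unknown status are a
#' configuration error unless already excluded. `by_quantile` ranks samples
#' by the driver gene's expression and labels the top `floor(fraction * n)`
#' (minimum 2) as high and the bottom as low, everything else excluded; ties
#' at a quantile boundary are broken by ascending sample identifier so the
#' assignment is deterministic under input reordering.
#'
#' @param x An expression matrix (any unit).
#' @param annotation Tibble with `sample_id` and `mycn_status`
#'   (`amplified` / `non_amplified` / `unknown`); every annotated sample must
#'   be a column of `x`.
#' @param mode `"by_status"` or `"by_quantile"`.
#' @param driver_gene_id Driver gene used by `by_quantile`.
#' @param quantile_fraction Fraction per tail for `by_quantile`, in (0, 0.5].
#' @return `annotation` with a `group_label` column
#'   (`high` / `low` / `excluded`).
#' @export
stratify <- function(x, annotation,
                     mode = c("by_status", "by_quantile"),
                     driver_gene_id = "MYCN",
                     quantile_fraction = 0.15) {
  mode <- match.arg(mode)
  if (!all(annotation$sample_id %in% expr_samples(x))) {
    missing <- setdiff(annotation$sample_id, expr_samples(x))
    abort_data(sprintf("Annotated sample(s) missing from the matrix: %s",
                       paste(missing, collapse = ", ")))
  }
  ann <- annotation
  if (mode == "by_status") {
    if (any(ann$mycn_status == "unknown")) {
      abort_config("by_status stratification cannot place samples with unknown status; exclude them first.")
    }
    ann$group_label <- dplyr::case_when(
      ann$mycn_status == "amplified" ~ "high",
      ann$mycn_status == "non_amplified" ~ "low",
      TRUE ~ "excluded"
    )
    if (sum(ann$group_label == "high") == 0 || sum(ann$group_label == "low") == 0) {
      abort_config("by_status stratification left a group empty.")
    }
  } else {
    check_fraction(quantile_fraction, "quantile_fraction", lo = 1e-9, hi = 0.5)
    if (!driver_gene_id %in% x$gene_id) {
      abort_config(sprintf("Driver gene '%s' is not in the matrix.", driver_gene_id))
    }
    expr <- unlist(x[x$gene_id == driver_gene_id, -1])[ann$sample_id]
    n <- nrow(ann)
    k <- max(2L, floor(quantile_fraction * n))
    if (2L * k > n) {
      abort_config(sprintf(
        "Quantile groups of %d samples each overlap with only %d samples.", k, n))
    }
    # one ascending ordering (driver expression, then sample id) keeps the
    # two tails disjoint and the assignment deterministic under ties
    ord <- order(expr, ann$sample_id)
    lab <- rep("excluded", n)
    lab[ord[seq_len(k)]] <- "low"
    lab[ord[seq(n - k + 1L, n)]] <- "high"
    ann$group_label <- lab
  }
  ann
}

#' Does a gene pass the differential-expression screen thresholds?
#'
#' Strict inequalities on both axes: `log_fc > min_log_fc` and
#' `adj_p < max_adj_p`. A log fold change of exactly the threshold fails.
#'
#' @param log_fc,adj_p Per-gene statistics (vectorised).
#' @param min_log_fc,max_adj_p Screen thresholds (defaults 1 and 0.05).
#' @return Logical vector.
#' @export
screen_pass <- function(log_fc, adj_p, min_log_fc = 1, max_adj_p = 0.05) {
  log_fc > min_log_fc & adj_p < max_adj_p
}

#' Run the stratified differential-expression screen
#'
#' Orchestrates the platform-appropriate pipeline: counts are transformed to
#' log-CPM and precision-weighted, intensities are modelled directly; both go
#' through the moderated two-group test and Benjamini-Hochberg adjustment,
#' then the strict screen thresholds.
#'
#' @param x An expression matrix (`raw_counts` or `normalized_intensity`).
#' @param groups A stratified annotation (from [stratify()]) or a character
#'   vector of `high`/`low`/`excluded` labels, one per sample.
#' @param min_log_fc,max_adj_p Screen thresholds, see [screen_pass()].
#' @param use_weights Whether to fit mean-variance precision weights
#'   (default: yes for counts, no for intensities).
#' @return An object of class `de_screen`: use [tidy()] for the full
#'   per-gene table (with `adj_p` and `pass`), [glance()] for a one-row
#'   summary, `$survivors` for the passing gene identifiers.
#' @export
differential_screen <- function(x, groups, min_log_fc = 1, max_adj_p = 0.05,
                                use_weights = NULL) {
  if (is.data.frame(groups)) {
    labels <- setNames(groups$group_label, groups$sample_id)[expr_samples(x)]
  } else {
    labels <- groups
  }
  is_counts <- identical(expr_unit(x), "raw_counts")
  if (is.null(use_weights)) use_weights <- is_counts
  y <- if (is_counts) log_cpm(x) else x
  w <- if (use_weights) fit_voom_weights(y, labels) else NULL
  tab <- moderated_t_test(y, labels, weights = w)
  tab$adj_p <- benjamini_hochberg(tab$raw_p)
  tab$pass <- screen_pass(tab$log_fc, tab$adj_p, min_log_fc, max_adj_p)
  structure(
    list(
      table = tab,
      survivors = tab$gene_id[tab$pass],
      thresholds = list(min_log_fc = min_log_fc, max_adj_p = max_adj_p),
      df_prior = attr(tab, "df_prior"),
      s2_prior = attr(tab, "s2_prior")
    ),
    class = "de_screen"
  )
}
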