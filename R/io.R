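#' Build a validated expression matrix
#'
#' An expression matrix is a tibble whose first column is `gene_id` and whose
#' remaining columns are one numeric column per sample, carrying a declared
#' unit. Values must be complete: missing values are rejected (imputation is
#' out of scope for this pipeline), as are duplicated gene or sample
#' identifiers. Counts and FPKM must be non-negative; `normalized_intensity`
#' is a log-scale unit and may be negative.
#'
#' @param data A data frame: first column gene identifiers, remaining columns
#'   numeric sample values.
#' @param unit Declared unit of the values. Operations that require counts
#'   (e.g. [log_cpm()]) reject matrices declared in other units.
#' @return A tibble of class `expr_mat` with a `unit` attribute.
#' @examples
#' expression_matrix(
#'   data.frame(gene_id = c("MYCN", "CAMKV"), s1 = c(10, 0), s2 = c(3, 7)),
#'   unit = "raw_counts"
#' )
#' @export
expression_matrix <- function(data,
                              unit = c("raw_counts", "fpkm", "normalized_intensity")) {
  unit <- match.arg(unit)
  if (!is.data.frame(data) || ncol(data) < 2L) {
    abort_format("An expression matrix needs a gene_id column plus at least one sample column.")
  }
  data <- as_tibble(data)
  names(data)[1] <- "gene_id"
  gene_id <- as.character(data$gene_id)
  dup_g <- unique(gene_id[duplicated(gene_id)])
  if (length(dup_g) > 0) {
    abort_format(sprintf("Duplicated gene identifier(s): %s", paste(dup_g, collapse = ", ")))
  }
  sample_ids <- names(data)[-1]
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0) {
    abort_format(sprintf("Duplicated sample identifier(s): %s", paste(dup_s, collapse = ", ")))
  }
  for (s in sample_ids) {
    v <- data[[s]]
    if (!is.numeric(v)) {
      abort_format(sprintf("Sample column '%s' is not numeric.", s))
    }
    if (anyNA(v)) {
      abort_format(sprintf(
        "Missing value for gene '%s' in sample '%s'; missing expression values are not permitted.",
        gene_id[which(is.na(v))[1]], s
      ))
    }
    if (unit != "normalized_intensity" && any(v < 0)) {
      abort_format(sprintf(
        "Negative value for gene '%s' in sample '%s'; %s values must be >= 0.",
        gene_id[which(v < 0)[1]], s, unit
      ))
    }
  }
  data$gene_id <- gene_id
  attr(data, "unit") <- unit
  class(data) <- unique(c("expr_mat", class(data)))
  data
}

#' Declared unit of an expression matrix
#' @param x An expression matrix built by [expression_matrix()].
#' @return One of `"raw_counts"`, `"fpkm"`, `"normalized_intensity"`.
#' @export
expr_unit <- function(x) attr(x, "unit", exact = TRUE) %||% NA_character_

# Internal accessors: values as a plain numeric matrix with gene rownames.
expr_values <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene_id
  m
}

expr_samples <- function(x) names(x)[-1]

# Rebuild an expr_mat from a numeric matrix (genes x samples).
expr_from_matrix <- function(m, unit, lib_size = NULL) {
  out <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(gene_id = rownames(m)), out)
  out <- expression_matrix(out, unit = unit)
  if (!is.null(lib_size)) attr(out, "lib_size") <- lib_size
  out
}

#' Read a gene-by-sample expression table
#'
#' Reads a tab-separated file whose first column is the gene identifier and
#' whose header row names the samples. The file is validated on the way in:
#' duplicate identifiers, negative values and non-numeric cells are format
#' errors reported with their row/column coordinates.
#'
#' @param path Path to a TSV file.
#' @inheritParams expression_matrix
#' @return A validated expression matrix (see [expression_matrix()]), with
#'   row and column order preserved from the file.
#' @export
read_expression_tsv <- function(path,
                                unit = c("raw_counts", "fpkm", "normalized_intensity")) {
  unit <- match.arg(unit)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2L) {
    abort_format(sprintf("'%s': expected a gene_id column plus sample columns.", path))
  }
  gene_id <- raw[[1]]
  out <- tibble(gene_id = gene_id)
  for (s in names(raw)[-1]) {
    txt <- raw[[s]]
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(num) & !is.na(txt))
    if (length(bad) > 0) {
      abort_format(sprintf(
        "'%s': non-numeric value '%s' for gene '%s' (row %d), sample '%s'.",
        path, txt[bad[1]], gene_id[bad[1]], bad[1], s
      ))
    }
    out[[s]] <- num
  }
  expression_matrix(out, unit = unit)
}

#' Write an expression matrix as TSV
#'
#' @param x An expression matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(as.data.frame(x)), path, progress = FALSE)
  invisible(path)
}

#' Read an ENCODE narrowPeak file
#'
#' narrowPeak is a 10-column BED extension: chrom, start, end, name, score,
#' strand, signal value, -log10(p), -log10(q), summit offset. Coordinates are
#' 0-based half-open and kept that way. The q-value is decoded to the linear
#' scale (`q_value = 10^-col9`); a summit offset of -1 (unknown) becomes `NA`.
#'
#' @param path Path to a narrowPeak file.
#' @return A tibble with one row per peak: `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `signal`, `p_log10`, `q_value` (linear scale),
#'   `summit_offset`.
#' @export
read_narrowpeak <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(empty_peaks())
  }
  if (ncol(raw) < 10L) {
    abort_format(sprintf("'%s': narrowPeak requires 10 columns, found %d.", path, ncol(raw)))
  }
  num <- function(i) {
    v <- suppressWarnings(as.numeric(raw[[i]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      abort_format(sprintf("'%s': non-numeric value in column %d, line %d.", path, i, bad[1]))
    }
    v
  }
  start <- num(2); end <- num(3)
  if (any(start < 0)) {
    abort_format(sprintf("'%s': negative start coordinate at line %d.", path, which(start < 0)[1]))
  }
  if (any(end <= start)) {
    abort_format(sprintf("'%s': end <= start at line %d.", path, which(end <= start)[1]))
  }
  summit <- num(10)
  tibble(
    chrom = raw[[1]],
    start = as.integer(start),
    end = as.integer(end),
    name = raw[[4]],
    score = num(5),
    strand = raw[[6]],
    signal = num(7),
    p_log10 = num(8),
    q_value = 10^(-num(9)),
    summit_offset = ifelse(summit < 0, NA_integer_, as.integer(summit))
  )
}

empty_peaks <- function() {
  tibble(
    chrom = character(), start = integer(), end = integer(), name = character(),
    score = double(), strand = character(), signal = double(),
    p_log10 = double(), q_value = double(), summit_offset = integer()
  )
}

#' Write peaks as an ENCODE narrowPeak file
#'
#' Inverse of [read_narrowpeak()]: linear q-values are re-encoded as
#' `-log10(q)` in column 9 and missing summit offsets as -1.
#'
#' @param peaks A peak tibble as returned by [read_narrowpeak()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- tibble(
    chrom = peaks$chrom,
    start = peaks$start,
    end = peaks$end,
    name = peaks$name %||% ".",
    score = peaks$score %||% 0,
    strand = peaks$strand %||% ".",
    signal = peaks$signal,
    p_log10 = peaks$p_log10 %||% -1,
    q_log10 = -log10(peaks$q_value),
    summit = ifelse(is.na(peaks$summit_offset), -1L, peaks$summit_offset)
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED3+ interval file
#'
#' Returns 0-based half-open intervals in file order. Empty intervals
#' (`end <= start`) and malformed coordinates are format errors.
#'
#' @param path Path to a BED file.
#' @return A tibble with `chrom`, `start`, `end` and, when present in the
#'   file, `name` and `strand`.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  if (ncol(raw) < 3L) {
    abort_format(sprintf("'%s': BED requires at least 3 columns.", path))
  }
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  bad <- which(is.na(start) | is.na(end) | start < 0)
  if (length(bad) > 0) {
    abort_format(sprintf("'%s': malformed coordinates at line %d.", path, bad[1]))
  }
  if (any(end <= start)) {
    abort_format(sprintf("'%s': empty or inverted interval (end <= start) at line %d.",
                         path, which(end <= start)[1]))
  }
  out <- tibble(chrom = raw[[1]], start = as.integer(start), end = as.integer(end))
  if (ncol(raw) >= 4L) out$name <- raw[[4]]
  if (ncol(raw) >= 6L) out$strand <- raw[[6]]
  out
}

#' Write intervals as BED
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  readr::write_tsv(intervals[, c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' @param path Path to a FASTA file of promoter sequences, one record per
#'   gene, named by gene identifier.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_promoter_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write promoter sequences to FASTA
#' @param promoters Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(promoters, path) {
  if (is.character(promoters)) {
    promoters <- Biostrings::DNAStringSet(promoters)
  }
  Biostrings::writeXStringSet(promoters, path)
  invisible(path)
}
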