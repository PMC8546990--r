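## Normalization, alpha-diversity, the multidiversity index, and the
## multinutrient cycling index (MNC).

#' Normalize an OTU count table to relative abundances
#'
#' `"tss"` divides each sample column by its total (total-sum scaling).
#' `"median_of_ratios"` first divides each column by its DESeq2-style size
#' factor (median of ratios to per-OTU geometric means, computed over OTUs
#' nonzero in all samples) and then renormalizes each column to sum to 1; the
#' size factors are kept in the `"size_factors"` attribute.
#'
#' @param x An `otu_table`.
#' @param method `"tss"` (default) or `"median_of_ratios"`.
#' @return A `rel_abundance_table`: list with `values` (columns sum to 1) and
#'   `kingdom`.
#' @export
normalize_counts <- function(x, method = c("tss", "median_of_ratios")) {
  stopifnot(inherits(x, "otu_table"))
  method <- match.arg(method)
  counts <- x$counts
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  sf <- NULL
  if (method == "median_of_ratios") {
    sf <- DESeq2::estimateSizeFactorsForMatrix(counts)
    counts <- sweep(counts, 2L, sf, "/")
    totals <- colSums(counts)
  }
  values <- sweep(counts, 2L, totals, "/")
  out <- rel_abundance_table(values, x$kingdom)
  if (!is.null(sf)) attr(out, "size_factors") <- sf
  out
}

#' Construct a relative-abundance table
#'
#' @param values Numeric matrix in \[0, 1\] with OTU rownames and sample
#'   colnames; each column must sum to `column_total` (within 1e-9).
#' @param kingdom Per-OTU kingdom labels (as in [otu_table()]).
#' @param column_total Expected column sum, 1 by default (2 for a stacked
#'   two-kingdom table from [combine_and_rescale()]).
#' @return A `rel_abundance_table`.
#' @export
rel_abundance_table <- function(values, kingdom, column_total = 1) {
  values <- as.matrix(values)
  if (any(values < 0) || anyNA(values)) stop("relative abundances must be in [0,1]")
  if (ncol(values) > 0L) {
    sums <- colSums(values)
    if (any(abs(sums - column_total) > 1e-9)) {
      stop("column sums must equal ", column_total, " (max deviation ",
           format(max(abs(sums - column_total))), ")")
    }
  }
  if (length(kingdom) == 1L) kingdom <- rep(kingdom, nrow(values))
  if (!is.null(names(kingdom))) kingdom <- kingdom[rownames(values)]
  names(kingdom) <- rownames(values)
  structure(list(values = values, kingdom = kingdom, column_total = column_total),
            class = "rel_abundance_table")
}

#' @export
print.rel_abundance_table <- function(x, ...) {
  cat(sprintf("rel_abundance_table: %d OTUs x %d samples (column total %g)\n",
              nrow(x$values), ncol(x$values), x$column_total))
  invisible(x)
}

#' Shannon diversity (natural log)
#'
#' `H = -sum(p * log(p))` with `0 * log(0) := 0`, in nats. For a matrix the
#' index is computed per sample column.
#'
#' @param p Probability vector summing to 1, or a relative-abundance matrix /
#'   `rel_abundance_table` (columns summing to 1).
#' @return Numeric value, or named vector per sample.
#' @export
shannon <- function(p) {
  if (inherits(p, "rel_abundance_table") || is.matrix(p)) {
    v <- .values(p)
    return(apply(v, 2L, shannon))
  }
  if (any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("proportions must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Observed richness
#'
#' Number of OTUs detected at or above `detection` reads. For a matrix the
#' count is per sample column.
#'
#' @param counts Integer vector, matrix, or `otu_table`.
#' @param detection Detection threshold in reads (default 1).
#' @return Integer value or named vector per sample.
#' @export
richness <- function(counts, detection = 1) {
  v <- if (is.numeric(counts) && is.null(dim(counts))) {
    return(sum(counts >= detection))
  } else {
    .values(counts)
  }
  colSums(v >= detection)
}

#' Min-max standardization across samples
#'
#' `STD = (X - Xmin) / (Xmax - Xmin)` with the minimum and maximum taken
#' across all samples in scope, so the smallest value maps to 0 and the
#' largest to 1. A constant vector is an error unless `constant_value` gives
#' a fallback.
#'
#' @param x Numeric vector (length >= 2).
#' @param constant_value Optional value (e.g. 0.5) returned for every sample
#'   when `max(x) == min(x)`; by default a constant vector errors.
#' @return Numeric vector in \[0, 1\] with attributes `x_min` and `x_max`.
#' @export
minmax_standardize <- function(x, constant_value = NULL) {
  if (length(x) < 2L) stop("need at least 2 samples to standardize")
  x_min <- min(x, na.rm = TRUE)
  x_max <- max(x, na.rm = TRUE)
  if (x_max == x_min) {
    if (is.null(constant_value)) {
      stop("constant vector: min-max standardization is undefined")
    }
    out <- rep(constant_value, length(x))
    out[is.na(x)] <- NA_real_
  } else {
    out <- (x - x_min) / (x_max - x_min)
  }
  names(out) <- names(x)
  attr(out, "x_min") <- x_min
  attr(out, "x_max") <- x_max
  out
}

#' Soil microbial multidiversity
#'
#' The mean of the min-max-standardized bacterial Shannon diversity and
#' fungal richness, standardized across all samples in scope; values lie in
#' \[0, 1\].
#'
#' @param shannon_bacteria Per-sample bacterial Shannon diversity (nats).
#' @param richness_fungi Per-sample fungal OTU richness.
#' @param constant_value Passed to [minmax_standardize()].
#' @return Named numeric vector of multidiversity values.
#' @export
multidiversity <- function(shannon_bacteria, richness_fungi,
                           constant_value = NULL) {
  if (length(shannon_bacteria) != length(richness_fungi)) {
    stop("diversity vectors must cover the same samples")
  }
  if (!is.null(names(shannon_bacteria)) && !is.null(names(richness_fungi))) {
    if (!identical(names(shannon_bacteria), names(richness_fungi))) {
      richness_fungi <- richness_fungi[names(shannon_bacteria)]
    }
  }
  sb <- minmax_standardize(shannon_bacteria, constant_value)
  rf <- minmax_standardize(richness_fungi, constant_value)
  out <- (as.numeric(sb) + as.numeric(rf)) / 2
  names(out) <- names(shannon_bacteria)
  out
}

#' Multinutrient cycling index (MNC)
#'
#' Each of the eight nutrient variables is min-max standardized across all
#' in-scope samples, and the MNC is the per-sample mean of the standardized
#' scores, so it lies in \[0, 1\]. Samples with any missing nutrient are
#' excluded (returned as `NA`) with a warning; they do not affect the
#' standardization of the remaining samples.
#'
#' @param nutrients Numeric matrix or data.frame, samples x nutrient
#'   variables (default columns [nutrient_vars()]), with sample ids as
#'   rownames.
#' @param vars Columns to use; defaults to the eight nutrient variables.
#' @param constant_value Passed to [minmax_standardize()].
#' @return Named numeric vector of MNC values (`NA` for incomplete samples).
#' @export
mnc <- function(nutrients, vars = nutrient_vars(), constant_value = NULL) {
  m <- as.matrix(as.data.frame(nutrients)[, vars, drop = FALSE])
  if (nrow(m) < 2L) stop("MNC needs at least 2 samples")
  complete <- complete.cases(m)
  if (!all(complete)) {
    warning(sum(!complete), " sample(s) with missing nutrients excluded from MNC")
  }
  out <- rep(NA_real_, nrow(m))
  if (sum(complete) >= 2L) {
    std <- apply(m[complete, , drop = FALSE], 2L, minmax_standardize,
                 constant_value = constant_value)
    out[complete] <- rowMeans(std)
  }
  names(out) <- rownames(m)
  out
}

#' Per-sample diversity and function records
#'
#' Convenience wrapper producing one row per sample with bacterial Shannon
#' diversity, fungal richness, multidiversity, and MNC, standardized across
#' all samples supplied.
#'
#' @param bacteria,fungi `otu_table` objects on the same samples.
#' @param samples Sample frame with `sample_id` and the nutrient columns.
#' @param normalization Normalization method for the bacterial table before
#'   Shannon diversity (see [normalize_counts()]).
#' @param detection Detection threshold for fungal richness.
#' @return A `data.frame` with columns `sample_id`, `shannon_bacteria`,
#'   `richness_fungi`, `multidiversity`, `mnc`.
#' @export
diversity_records <- function(bacteria, fungi, samples,
                              normalization = "tss", detection = 1) {
  ids <- sample_ids(bacteria)
  if (!setequal(ids, sample_ids(fungi))) stop("kingdom tables cover different samples")
  if (!all(ids %in% samples$sample_id)) {
    stop("samples missing from the sample frame: ",
         paste(head(setdiff(ids, samples$sample_id), 5L), collapse = ", "))
  }
  h <- shannon(normalize_counts(bacteria, normalization))
  r <- richness(subset_table(fungi, samples = ids), detection = detection)
  md <- multidiversity(h, r)
  nut <- as.matrix(samples[match(ids, samples$sample_id), nutrient_vars()])
  rownames(nut) <- ids
  data.frame(sample_id = ids,
             shannon_bacteria = unname(h),
             richness_fungi = unname(r),
             multidiversity = unname(md),
             mnc = unname(mnc(nut)),
             stringsAsFactors = FALSE)
}
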