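## Combined-kingdom beta-diversity: Bray-Curtis dissimilarity, NMDS axis 1
## with a deterministic sign convention, and ANOSIM group testing.

#' Stack per-kingdom relative-abundance tables
#'
#' Each kingdom is standardized to a total abundance of 1 per sample before
#' stacking, so the stacked columns sum to 2; with `renormalize = TRUE` the
#' stacked table is rescaled so columns sum to 1. Kingdom-wise totals are
#' preserved by the stacking.
#'
#' @param bacteria,fungi `rel_abundance_table` objects (columns summing to 1)
#'   on the same sample set.
#' @param renormalize Rescale stacked columns to sum to 1 (default `FALSE`,
#'   i.e. the literal sum-2 stacking).
#' @return A `rel_abundance_table` with `column_total` 2 (or 1).
#' @export
combine_and_rescale <- function(bacteria, fungi, renormalize = FALSE) {
  stopifnot(inherits(bacteria, "rel_abundance_table"),
            inherits(fungi, "rel_abundance_table"))
  sb <- colnames(bacteria$values)
  if (!setequal(sb, colnames(fungi$values))) {
    stop("sample sets differ between the kingdom tables")
  }
  vb <- bacteria$values
  vf <- fungi$values[, sb, drop = FALSE]
  clash <- intersect(rownames(vb), rownames(vf))
  if (length(clash)) {
    rownames(vb)[rownames(vb) %in% clash] <- paste0("bacteria|", clash)
    rownames(vf)[rownames(vf) %in% clash] <- paste0("fungi|", clash)
  }
  values <- rbind(vb, vf)
  kingdom <- setNames(c(rep("bacteria", nrow(vb)), rep("fungi", nrow(vf))),
                      rownames(values))
  total <- 2
  if (renormalize) {
    values <- values / 2
    total <- 1
  }
  rel_abundance_table(values, kingdom, column_total = total)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over OTUs, computed with
#' `vegan::vegdist`. Values are in \[0, 1\]; a pair of all-zero samples is
#' undefined and raises an error.
#'
#' @param x A `rel_abundance_table`, `otu_table`, or OTU-by-sample matrix.
#' @return A `dist` object labelled by sample id.
#' @export
bray_curtis <- function(x) {
  v <- .values(x)
  if (ncol(v) < 2L) stop("need at least 2 samples")
  zero <- colSums(v) == 0
  if (sum(zero) >= 2L) {
    stop("Bray-Curtis undefined for pairs of all-zero samples: ",
         paste(colnames(v)[zero], collapse = ", "))
  }
  vegan::vegdist(t(v), method = "bray")
}

#' NMDS axis-1 scores with a deterministic orientation
#'
#' Non-metric multidimensional scaling (via `vegan::metaMDS`) by stress
#' minimization with random restarts; the best-stress solution is kept. NMDS
#' axis signs are arbitrary, so axis 1 is oriented such that its Spearman
#' correlation with the most abundant OTU's per-sample abundance is >= 0
#' (the anchor OTU id is recorded); without an abundance table the axis is
#' returned unoriented.
#'
#' @param d A `dist` of sample dissimilarities.
#' @param rel Optional `rel_abundance_table` (or matrix) used for the
#'   orientation anchor.
#' @param k Number of dimensions (>= 2, default 2).
#' @param n_restarts Random restarts (default 20).
#' @param maxit Maximum iterations per start.
#' @param seed Integer seed (mandatory for reproducible scores).
#' @return List of class `nmds_axis`: `scores` (named axis-1 scores),
#'   `points` (all k axes), `stress`, `k`, `seed`, `anchor`.
#' @export
nmds_axis1 <- function(d, rel = NULL, k = 2, n_restarts = 20, maxit = 300,
                       seed = 1) {
  stopifnot(inherits(d, "dist"), k >= 2)
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, trymax = n_restarts, maxit = maxit,
                        trace = 0)
  scores <- fit$points[, 1L]
  anchor <- NA_character_
  if (!is.null(rel)) {
    v <- .values(rel)
    anchor <- rownames(v)[which.max(rowSums(v))]
    ab <- v[anchor, names(scores)]
    rho <- suppressWarnings(cor(scores, ab, method = "spearman"))
    if (!is.na(rho) && rho < 0) {
      scores <- -scores
      fit$points[, 1L] <- -fit$points[, 1L]
    }
  }
  if (any(!is.finite(scores))) stop("non-finite NMDS scores")
  structure(list(scores = scores, points = fit$points, stress = fit$stress,
                 k = k, seed = seed, anchor = anchor),
            class = "nmds_axis")
}

#' @export
print.nmds_axis <- function(x, ...) {
  cat(sprintf("NMDS (k=%d): %d samples, stress %.4f, anchor OTU %s\n",
              x$k, length(x$scores), x$stress, x$anchor))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of group differences in a dissimilarity matrix:
#' `R = (mean between-group rank - mean within-group rank) / (M/2)` with
#' `M = n(n-1)/2`, and a permutation p-value with the +1 correction
#' (`p = (1 + #{perm R >= obs}) / (1 + n_perm)`), computed with
#' `vegan::anosim`.
#'
#' @param d A `dist` of sample dissimilarities.
#' @param groups Group labels, one per sample (>= 2 groups, each n >= 2).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List with elements `R`, `p`, `n_perm`, and `perm` (the permutation
#'   distribution of R).
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1) {
  stopifnot(inherits(d, "dist"))
  groups <- factor(groups)
  if (length(groups) != attr(d, "Size")) stop("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) {
    stop("every group needs n >= 2; offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  set.seed(seed)
  fit <- vegan::anosim(d, grouping = groups, permutations = n_perm)
  list(R = unname(fit$statistic), p = fit$signif, n_perm = n_perm,
       perm = fit$perm)
}
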