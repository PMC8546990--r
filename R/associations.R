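## Prevalence-filtered all-pairs Spearman association networks with FDR
## control; kingdom-partitioned positive/negative edge counts and the
## negative-association proportion.

#' Prevalence filter
#'
#' Keeps OTUs detected in more than `threshold` of the samples (strictly
#' greater than, the literal "more than" reading; `strict = FALSE` switches
#' to >=).
#'
#' @param x An `otu_table`.
#' @param threshold Prevalence threshold in (0, 1), default 0.60.
#' @param strict Use `>` (default) rather than `>=`.
#' @param detection Detection threshold in reads.
#' @return A filtered `otu_table`.
#' @export
prevalence_filter <- function(x, threshold = 0.60, strict = TRUE,
                              detection = 1) {
  stopifnot(inherits(x, "otu_table"), threshold > 0, threshold < 1)
  prev <- rowMeans(x$counts >= detection)
  keep <- if (strict) prev > threshold else prev >= threshold
  if (!any(keep)) {
    stop("no OTU passes the prevalence filter at ", threshold,
         "; consider lowering the threshold")
  }
  subset_table(x, otus = which(keep))
}

#' All-pairs Spearman associations with FDR control
#'
#' Computes Spearman's rho (average ranks for ties) for every unordered OTU
#' pair, a two-sided p-value from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom, and
#' FDR-adjusted q-values over all tested pairs. Edges with `q < q_threshold`
#' (and `|rho| > rho_threshold`, if set) are retained. Pairs involving a
#' zero-variance OTU cannot be ranked and are skipped (tallied in
#' `params$n_pairs_skipped`).
#'
#' @param x An `otu_table` or `rel_abundance_table` (associations are
#'   conventionally computed on relative abundances).
#' @param q_threshold FDR threshold (default 0.01, strict `<`).
#' @param fdr_method Method passed to [stats::p.adjust()] (default `"BH"`).
#' @param rho_threshold Optional minimum `|rho|` (default 0 = none).
#' @return List of class `edge_set`: `edges` (data.frame `otu_a`, `otu_b`,
#'   `kingdom_a`, `kingdom_b`, `rho`, `p_raw`, `q_fdr`, `sign`) and `params`.
#' @export
spearman_edges <- function(x, q_threshold = 0.01, fdr_method = "BH",
                           rho_threshold = 0) {
  v <- .values(x)
  kingdom <- if (inherits(x, "otu_table") || inherits(x, "rel_abundance_table")) {
    x$kingdom
  } else {
    setNames(rep(NA_character_, nrow(v)), rownames(v))
  }
  n <- ncol(v)
  if (nrow(v) < 2L) stop("need at least 2 OTUs")
  if (n < 5L) warning("fewer than 5 samples; correlations will be unstable")

  sds <- apply(v, 1L, sd)
  ok <- sds > 0
  n_zero <- sum(!ok)
  n_total_pairs <- choose(nrow(v), 2L)
  n_skipped <- n_total_pairs - choose(sum(ok), 2L)
  vv <- v[ok, , drop = FALSE]

  rho <- suppressWarnings(cor(t(vv), method = "spearman"))
  iu <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[iu]
  r_cl <- pmin(pmax(r, -1), 1)
  tstat <- r_cl * sqrt((n - 2) / pmax(1 - r_cl^2, .Machine$double.eps))
  p_raw <- 2 * pt(-abs(tstat), df = n - 2)
  p_raw[abs(r_cl) >= 1] <- 0
  q <- p.adjust(p_raw, method = fdr_method)

  a_id <- rownames(vv)[iu[, 1L]]
  b_id <- rownames(vv)[iu[, 2L]]
  swap <- a_id > b_id                 # canonical ordering otu_a < otu_b
  tmp <- a_id[swap]; a_id[swap] <- b_id[swap]; b_id[swap] <- tmp

  keep <- q < q_threshold & abs(r) > rho_threshold & r != 0
  edges <- data.frame(
    otu_a = a_id[keep], otu_b = b_id[keep],
    kingdom_a = unname(kingdom[a_id[keep]]),
    kingdom_b = unname(kingdom[b_id[keep]]),
    rho = r[keep], p_raw = p_raw[keep], q_fdr = q[keep],
    sign = ifelse(r[keep] < 0, "neg", "pos"),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$otu_a, edges$otu_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    edges = edges,
    params = list(q_threshold = q_threshold, fdr_method = fdr_method,
                  rho_threshold = rho_threshold, n_samples = n,
                  n_pairs_tested = choose(sum(ok), 2L),
                  n_pairs_skipped = n_skipped,
                  n_zero_variance_otus = n_zero),
    p_raw_all = p_raw
  ), class = "edge_set")
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("edge_set: %d edges at q < %g (%s) over %d tested pairs (n = %d samples)\n",
              nrow(x$edges), x$params$q_threshold, x$params$fdr_method,
              x$params$n_pairs_tested, x$params$n_samples))
  invisible(x)
}

#' Kingdom-partitioned association counts
#'
#' Counts negative and positive edges in the partitions `all`, `bacterial`
#' (both endpoints bacterial), `fungal`, and `bacterial_fungal`
#' (cross-kingdom), with the negative-association proportion
#' `pro = neg / (neg + pos)` (full precision; `NA` for an empty partition).
#' The `all` counts equal the sum of the three sub-partitions.
#'
#' @param e An `edge_set` whose edges carry kingdom labels.
#' @return Data frame `(partition, neg, pos, pro)`.
#' @export
partition_and_count <- function(e) {
  stopifnot(inherits(e, "edge_set"))
  ed <- e$edges
  part <- function(sel) {
    neg <- sum(sel & ed$sign == "neg")
    pos <- sum(sel & ed$sign == "pos")
    c(neg = neg, pos = pos)
  }
  both_b <- ed$kingdom_a == "bacteria" & ed$kingdom_b == "bacteria"
  both_f <- ed$kingdom_a == "fungi" & ed$kingdom_b == "fungi"
  cross <- ed$kingdom_a != ed$kingdom_b
  m <- rbind(all = part(rep(TRUE, nrow(ed))),
             bacterial = part(both_b),
             fungal = part(both_f),
             bacterial_fungal = part(cross))
  tot <- m[, "neg"] + m[, "pos"]
  data.frame(partition = rownames(m),
             neg = unname(m[, "neg"]), pos = unname(m[, "pos"]),
             pro = ifelse(tot > 0, m[, "neg"] / tot, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

## Internal: association summary for one set of samples.
.group_association_summary <- function(bacteria, fungi, ids, prevalence,
                                       strict, q_threshold, fdr_method,
                                       normalization = "tss") {
  b <- prevalence_filter(subset_table(bacteria, samples = ids),
                         threshold = prevalence, strict = strict)
  f <- prevalence_filter(subset_table(fungi, samples = ids),
                         threshold = prevalence, strict = strict)
  rel <- combine_and_rescale(normalize_counts(b, normalization),
                             normalize_counts(f, normalization))
  e <- spearman_edges(rel, q_threshold = q_threshold, fdr_method = fdr_method)
  list(summary = partition_and_count(e), edges = e)
}

#' Association summaries per habitat and soil layer
#'
#' For each habitat and each scope (`whole` = both layers pooled, `up`,
#' `down`), applies the prevalence filter within the group's samples,
#' normalizes each kingdom to relative abundance, stacks the kingdoms, and
#' tabulates the kingdom-partitioned significant associations. Groups below
#' `min_n` samples (or in which a kingdom loses all OTUs to the filter) are
#' skipped with a warning.
#'
#' @param bacteria,fungi `otu_table` objects on the same samples.
#' @param samples Sample frame with `sample_id`, `habitat`, `layer`.
#' @param prevalence,strict Prevalence filter settings (see
#'   [prevalence_filter()]).
#' @param q_threshold,fdr_method FDR settings (see [spearman_edges()]).
#' @param min_n Minimum samples per group (default 10).
#' @param scopes Layer scopes to summarize (default whole/up/down).
#' @return Data frame `(habitat, layer, partition, neg, pos, pro)`.
#' @export
summarize_groups <- function(bacteria, fungi, samples, prevalence = 0.60,
                             strict = TRUE, q_threshold = 0.01,
                             fdr_method = "BH", min_n = 10,
                             scopes = .scopes) {
  out <- list()
  for (hab in unique(samples$habitat)) {
    for (scope in scopes) {
      sel <- samples$habitat == hab &
        (scope == "whole" | samples$layer == scope)
      ids <- samples$sample_id[sel]
      ids <- intersect(ids, sample_ids(bacteria))
      if (length(ids) < min_n) {
        warning(sprintf("group %s/%s has %d samples (< %d); skipped",
                        hab, scope, length(ids), min_n))
        next
      }
      res <- tryCatch(
        .group_association_summary(bacteria, fungi, ids, prevalence, strict,
                                   q_threshold, fdr_method),
        error = function(err) {
          warning(sprintf("group %s/%s skipped: %s", hab, scope,
                          conditionMessage(err)))
          NULL
        })
      if (is.null(res)) next
      s <- res$summary
      out[[paste(hab, scope, sep = ":")]] <-
        data.frame(habitat = hab, layer = scope, s, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no group produced an association summary")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
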