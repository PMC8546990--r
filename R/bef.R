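## Group-level diversity-function correlations and the meta-analysis linking
## their strength to neutral-model fit and the negative bacterial-fungal
## association proportion, with random-forest predictor importance.

#' Per-group Pearson correlations
#'
#' Pearson r and two-sided p (t distribution, df = n - 2) of `x` vs `y`
#' within each group. Groups below `min_n` paired finite observations, or
#' with zero variance in either variable, yield `NA` with a warning.
#'
#' @param x,y Numeric vectors.
#' @param groups Group labels aligned with `x`/`y`.
#' @param min_n Minimum paired observations per group (default 5).
#' @return Data frame `(group, r, p, n)`.
#' @export
group_correlation <- function(x, y, groups, min_n = 5) {
  stopifnot(length(x) == length(y), length(x) == length(groups))
  out <- lapply(unique(groups), function(g) {
    sel <- groups == g & is.finite(x) & is.finite(y)
    n <- sum(sel)
    r <- p <- NA_real_
    if (n >= min_n) {
      if (sd(x[sel]) == 0 || sd(y[sel]) == 0) {
        warning("zero variance in group ", g, "; correlation undefined")
      } else {
        ct <- cor.test(x[sel], y[sel], method = "pearson")
        r <- unname(ct$estimate)
        p <- ct$p.value
      }
    }
    data.frame(group = g, r = r, p = p, n = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assemble group-level records for the meta-analysis
#'
#' Joins the per-stage outputs into one row per (habitat x scope), where the
#' scope is `whole` (both layers), `up`, or `down`: the Pearson correlation
#' of multidiversity vs MNC (`r_alpha`), of the NMDS axis-1 score vs MNC
#' (`r_beta`, signed under the axis orientation convention, with `r_beta_abs`
#' also reported since the NMDS sign is arbitrary), the group's neutral-model
#' fit (`neutral_m`, `neutral_r2`), the negative bacterial-fungal association
#' proportion (`neg_bf_pro`), and group means of pH and moisture. Groups
#' missing a component keep the record with `NA` in that field.
#'
#' @param diversity Data frame from [diversity_records()].
#' @param ordination An `nmds_axis` object, or `NULL` to skip `r_beta`.
#' @param fits Data frame from [compare_fits()] (columns `habitat`, `layer`,
#'   `m`, `r2`), or `NULL`.
#' @param association_summary Data frame from [summarize_groups()], or
#'   `NULL`.
#' @param samples Sample frame with `sample_id`, `habitat`, `layer`, `pH`,
#'   `moisture`.
#' @param scopes Scopes to emit (default whole/up/down).
#' @param min_n Minimum samples per group for the correlations.
#' @return Data frame of class `bef_records`.
#' @export
assemble_bef_records <- function(diversity, ordination = NULL, fits = NULL,
                                 association_summary = NULL, samples,
                                 scopes = .scopes, min_n = 5) {
  div <- diversity[match(samples$sample_id, diversity$sample_id), ]
  axis1 <- if (!is.null(ordination)) {
    ordination$scores[samples$sample_id]
  } else {
    rep(NA_real_, nrow(samples))
  }
  bf <- if (!is.null(association_summary)) {
    association_summary[association_summary$partition == "bacterial_fungal", ]
  } else {
    NULL
  }
  rows <- list()
  for (hab in unique(samples$habitat)) {
    for (scope in scopes) {
      sel <- samples$habitat == hab & (scope == "whole" | samples$layer == scope)
      n <- sum(sel)
      if (n == 0L) next
      corr <- function(a, b) {
        ok <- sel & is.finite(a) & is.finite(b)
        if (sum(ok) < min_n || sd(a[ok]) == 0 || sd(b[ok]) == 0) {
          return(c(NA_real_, NA_real_))
        }
        ct <- cor.test(a[ok], b[ok])
        c(unname(ct$estimate), ct$p.value)
      }
      ra <- corr(div$multidiversity, div$mnc)
      rb <- corr(axis1, div$mnc)
      fit_row <- if (!is.null(fits)) {
        fits[fits$habitat == hab & fits$layer == scope, , drop = FALSE]
      } else {
        NULL
      }
      bf_row <- if (!is.null(bf)) {
        bf[bf$habitat == hab & bf$layer == scope, , drop = FALSE]
      } else {
        NULL
      }
      rows[[paste(hab, scope, sep = ":")]] <- data.frame(
        habitat = hab, layer = scope, n_samples = n,
        r_alpha = ra[1L], p_alpha = ra[2L],
        r_beta = rb[1L], p_beta = rb[2L],
        r_beta_abs = abs(rb[1L]),
        neutral_m = if (!is.null(fit_row) && nrow(fit_row)) fit_row$m[1L] else NA_real_,
        neutral_r2 = if (!is.null(fit_row) && nrow(fit_row)) fit_row$r2[1L] else NA_real_,
        neg_bf_pro = if (!is.null(bf_row) && nrow(bf_row)) bf_row$pro[1L] else NA_real_,
        mean_ph = mean(samples$pH[sel]),
        mean_moisture = mean(samples$moisture[sel]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no overlapping groups between the inputs")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("bef_records", "data.frame")
  out
}

#' Meta-level Pearson correlation across group records
#'
#' Correlates two fields of the group-level record table across groups
#' (habitat x scope points), dropping records with `NA` in either field.
#'
#' @param records A `bef_records` data frame.
#' @param x_field,y_field Column names to correlate.
#' @return List: `r`, `p`, `n`, `n_dropped`.
#' @export
meta_correlation <- function(records, x_field, y_field) {
  x <- records[[x_field]]
  y <- records[[y_field]]
  if (is.null(x) || is.null(y)) stop("unknown field name")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 4L) stop("need at least 4 non-NA group records, have ", sum(ok))
  ct <- cor.test(x[ok], y[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       n_dropped = sum(!ok))
}

#' Random-forest predictor importance with permutation significance
#'
#' Fits a regression random forest of `response` on `predictors` over the
#' group records and reports each predictor's %IncMSE importance (increase
#' in out-of-bag MSE when the predictor is permuted, averaged over trees).
#' Significance is assessed by refitting the forest on `n_perm` permutations
#' of the response: each predictor's p-value is the +1-corrected fraction of
#' null importances at least as large as observed, and the model p-value
#' compares the observed out-of-bag variance explained with its null
#' distribution. `n_perm = 0` skips the permutation step (p-values `NA`).
#'
#' @param records A `bef_records` data frame (or any data.frame).
#' @param predictors Predictor column names (default: negative
#'   bacterial-fungal proportion, neutral R2, pH, moisture).
#' @param response Response column name (default `"r_alpha"`).
#' @param n_trees Trees per forest (default 5000, the conventional setting
#'   for importance stability).
#' @param n_perm Response permutations (default 1000).
#' @param seed Integer seed; output is seed-reproducible.
#' @return Data frame `(predictor, pct_inc_mse, p_perm)` sorted by
#'   decreasing importance, with attributes `model_p_perm` and
#'   `model_var_explained`.
#' @export
predictor_importance <- function(records,
                                 predictors = c("neg_bf_pro", "neutral_r2",
                                                "mean_ph", "mean_moisture"),
                                 response = "r_alpha",
                                 n_trees = 5000, n_perm = 1000, seed = 1) {
  df <- as.data.frame(records)[, c(predictors, response)]
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 8L) {
    stop("need at least 8 complete-case records, have ", nrow(df))
  }
  x <- df[, predictors, drop = FALSE]
  y <- df[[response]]
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                    importance = TRUE)
  imp <- randomForest::importance(fit, type = 1)[, 1L]
  imp[!is.finite(imp)] <- 0   # a predictor never used by the forest
  obs_var <- 1 - mean((y - fit$predicted)^2) / var(y)

  p_perm <- rep(NA_real_, length(predictors))
  model_p <- NA_real_
  if (n_perm > 0) {
    null_imp <- matrix(NA_real_, nrow = n_perm, ncol = length(predictors))
    null_var <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      yb <- sample(y)
      fb <- randomForest::randomForest(x = x, y = yb, ntree = n_trees,
                                       importance = TRUE)
      ni <- randomForest::importance(fb, type = 1)[, 1L]
      ni[!is.finite(ni)] <- 0
      null_imp[b, ] <- ni
      null_var[b] <- 1 - mean((yb - fb$predicted)^2) / var(yb)
    }
    p_perm <- vapply(seq_along(predictors), function(j) {
      (1 + sum(null_imp[, j] >= imp[j])) / (1 + n_perm)
    }, numeric(1L))
    model_p <- (1 + sum(null_var >= obs_var)) / (1 + n_perm)
  }
  out <- data.frame(predictor = predictors, pct_inc_mse = unname(imp),
                    p_perm = p_perm, stringsAsFactors = FALSE)
  out <- out[order(-out$pct_inc_mse), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "model_p_perm") <- model_p
  attr(out, "model_var_explained") <- obs_var
  attr(out, "n_records") <- nrow(df)
  out
}

#' Run the full pipeline from tables to group-level records
#'
#' Orchestrates the stages on a two-kingdom study: per-sample diversity and
#' MNC (standardized across all samples), optionally the combined-kingdom
#' NMDS axis-1 score, per-group Sloan neutral fits on the merged count
#' table, per-group association summaries, and the join into `bef_records`.
#'
#' @param bacteria,fungi `otu_table` objects on the same samples.
#' @param samples Sample frame.
#' @param scopes Group scopes (default whole/up/down).
#' @param include_beta Compute the NMDS axis and `r_beta` (default `TRUE`;
#'   the costliest stage).
#' @param prevalence,q_threshold,fdr_method Network settings.
#' @param min_n_assoc Minimum samples per group for the network stage.
#' @param min_n Minimum samples per group for correlations.
#' @param n_restarts NMDS random restarts.
#' @param seed Seed for the NMDS stage.
#' @return A `bef_records` data frame; stage outputs in attribute
#'   `"stages"`.
#' @export
run_bef_pipeline <- function(bacteria, fungi, samples, scopes = .scopes,
                             include_beta = TRUE, prevalence = 0.60,
                             q_threshold = 0.01, fdr_method = "BH",
                             min_n_assoc = 10, min_n = 5, n_restarts = 20,
                             seed = 1) {
  div <- diversity_records(bacteria, fungi, samples)

  ord <- NULL
  rel <- combine_and_rescale(normalize_counts(bacteria, "tss"),
                             normalize_counts(fungi, "tss"))
  if (include_beta) {
    ord <- nmds_axis1(bray_curtis(rel), rel = rel, n_restarts = n_restarts,
                      seed = seed)
  }

  merged <- merge_kingdom_tables(bacteria, fungi)
  fits <- list()
  for (hab in unique(samples$habitat)) {
    for (scope in scopes) {
      sel <- samples$habitat == hab & (scope == "whole" | samples$layer == scope)
      ids <- samples$sample_id[sel]
      if (length(ids) < 2L) next
      prof <- occurrence_profiles(subset_table(merged, samples = ids))
      fits[[paste(hab, scope, sep = ":")]] <-
        suppressWarnings(fit_neutral_model(prof))
    }
  }
  fit_table <- if (length(fits) >= 2L) compare_fits(fits) else NULL

  assoc <- suppressWarnings(
    summarize_groups(bacteria, fungi, samples, prevalence = prevalence,
                     q_threshold = q_threshold, fdr_method = fdr_method,
                     min_n = min_n_assoc, scopes = scopes))

  records <- assemble_bef_records(div, ord, fit_table, assoc, samples,
                                  scopes = scopes, min_n = min_n)
  attr(records, "stages") <- list(diversity = div, ordination = ord,
                                  fits = fit_table, associations = assoc)
  records
}
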