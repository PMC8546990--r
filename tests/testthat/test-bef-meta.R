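test_that("group_correlation returns exact r for linear data and NA for degenerate", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  g <- rep(c("A", "B"), each = 4)
  out <- group_correlation(x, 2 * x + 1, g, min_n = 4)
  expect_equal(out$r, c(1, 1), tolerance = 1e-12)
  suppressWarnings(out2 <- group_correlation(x, rep(3, 8), g, min_n = 4))
  expect_true(all(is.na(out2$r)))

  # r matches the covariance / (sd sd) formula on a 6-point fixture
  xx <- c(0.1, 0.9, 0.4, 0.7, 0.2, 0.6)
  yy <- c(1.2, 2.3, 1.1, 2.0, 1.6, 1.7)
  out3 <- group_correlation(xx, yy, rep("G", 6), min_n = 5)
  r_manual <- sum((xx - mean(xx)) * (yy - mean(yy))) /
    sqrt(sum((xx - mean(xx))^2) * sum((yy - mean(yy))^2))
  expect_equal(out3$r, r_manual, tolerance = 1e-12)
  # groups below min_n give NA
  out4 <- group_correlation(xx, yy, c(rep("G", 5), "H"), min_n = 5)
  expect_true(is.na(out4$r[out4$group == "H"]))
})

test_that("assemble_bef_records joins stage outputs field by field", {
  s <- tiny_study(seed = 4, n_samples = 12, S = 150)
  rec <- run_bef_pipeline(s$bacteria, s$fungi, s$samples,
                          include_beta = TRUE, min_n_assoc = 10,
                          n_restarts = 5, seed = 1)
  stages <- attr(rec, "stages")
  # every habitat x scope present
  expect_identical(nrow(rec), 6L)   # 2 habitats x 3 scopes
  # joined fields equal the stage outputs they came from
  for (i in seq_len(nrow(rec))) {
    hab <- rec$habitat[i]; scope <- rec$layer[i]
    fit_row <- stages$fits[stages$fits$habitat == hab & stages$fits$layer == scope, ]
    if (nrow(fit_row)) expect_equal(rec$neutral_r2[i], fit_row$r2)
    bf <- stages$associations
    bf_row <- bf[bf$habitat == hab & bf$layer == scope &
                   bf$partition == "bacterial_fungal", ]
    if (nrow(bf_row)) expect_equal(rec$neg_bf_pro[i], bf_row$pro)
    sel <- s$samples$habitat == hab &
      (scope == "whole" | s$samples$layer == scope)
    expect_equal(rec$mean_ph[i], mean(s$samples$pH[sel]), tolerance = 1e-12)
    div <- stages$diversity[match(s$samples$sample_id[sel], stages$diversity$sample_id), ]
    expect_equal(rec$r_alpha[i], cor(div$multidiversity, div$mnc), tolerance = 1e-12)
  }
  # r_beta is computed against the recorded NMDS axis
  expect_true(all(is.finite(rec$r_beta)))
  expect_equal(rec$r_beta_abs, abs(rec$r_beta))
})

test_that("a full design yields one record per habitat and scope", {
  des <- study_design(n_samples = 10, ph_mean = 8, moisture_mean = 0.15)
  st <- generate_study(des, S = 120, n_reads = 2000, n_pairs = 8, seed = 6)
  rec <- run_bef_pipeline(st$bacteria, st$fungi, st$samples,
                          include_beta = FALSE, min_n_assoc = 10)
  expect_identical(nrow(rec), 15L)  # 5 habitats x {whole, up, down}
  expect_setequal(rec$layer, c("whole", "up", "down"))
})

test_that("meta_correlation reproduces exact relationships and a calibrated null", {
  rec <- data.frame(neg_bf_pro = seq(0.1, 0.9, length.out = 12))
  rec$r_alpha <- -rec$neg_bf_pro
  mc <- meta_correlation(rec, "neg_bf_pro", "r_alpha")
  expect_equal(mc$r, -1, tolerance = 1e-12)
  expect_identical(mc$n, 12L)
  expect_error(meta_correlation(rec[1:3, ], "neg_bf_pro", "r_alpha"), "at least 4")

  # permutation null: p-values approximately uniform
  set.seed(61)
  x <- rnorm(15)
  y <- rnorm(15)
  ps <- replicate(500, {
    cor.test(x, sample(y))$p.value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
  expect_lt(abs(mean(ps < 0.1) - 0.1), 0.06)
})

test_that("predictor importance recovers a planted driver and is deterministic", {
  set.seed(71)
  first <- 0
  for (s in 1:10) {
    n <- 15
    rec <- data.frame(neg_bf_pro = runif(n), neutral_r2 = runif(n),
                      mean_ph = rnorm(n, 8, 0.3), mean_moisture = runif(n))
    rec$r_alpha <- -2 * rec$neg_bf_pro + rnorm(n, 0, 0.15)
    imp <- predictor_importance(rec, n_trees = 500, n_perm = 0, seed = s)
    first <- first + (imp$predictor[1] == "neg_bf_pro")
  }
  expect_gte(first, 9)

  rec <- data.frame(neg_bf_pro = runif(12), neutral_r2 = runif(12),
                    mean_ph = rnorm(12, 8, 0.3), mean_moisture = runif(12))
  rec$r_alpha <- rec$neg_bf_pro + rnorm(12, 0, 0.1)
  i1 <- predictor_importance(rec, n_trees = 300, n_perm = 19, seed = 5)
  i2 <- predictor_importance(rec, n_trees = 300, n_perm = 19, seed = 5)
  expect_identical(i1, i2)
  expect_true(all(i1$p_perm > 0 & i1$p_perm <= 1))
  expect_error(predictor_importance(rec[1:5, ], n_perm = 0), "at least 8")
})

test_that("a pure-noise response is rarely called significant", {
  set.seed(81)
  hits <- 0
  n_runs <- 50
  for (s in 1:n_runs) {
    rec <- data.frame(neg_bf_pro = runif(12), neutral_r2 = runif(12),
                      mean_ph = rnorm(12, 8, 0.3), mean_moisture = runif(12),
                      r_alpha = rnorm(12))
    imp <- predictor_importance(rec, n_trees = 200, n_perm = 49, seed = s)
    hits <- hits + (attr(imp, "model_p_perm") <= 0.05)
  }
  expect_gte(1 - hits / n_runs, 0.9)
})

test_that("leave-one-out stability of group correlations on an adequate fixture", {
  set.seed(91)
  x <- runif(10)
  y <- 0.8 * x + rnorm(10, 0, 0.2)
  r_full <- cor(x, y)
  for (i in 1:10) {
    r_loo <- cor(x[-i], y[-i])
    expect_lt(abs(r_loo - r_full), 2 / (5 - 2))
  }
})

test_that("fit to the neutral model tracks the diversity-function link when planted in lockstep", {
  # migration rate and nutrient coupling ascend together across habitats, so
  # group-level neutral R2 and r(multidiversity, MNC) should co-vary
  hits <- 0
  for (s in 1:10) {
    des <- study_design(m_up = c(0.005, 0.012, 0.03, 0.08, 0.3),
                        pro_neg = rep(0.5, 5),
                        beta_mnc = c(0, 0.25, 0.5, 0.75, 1.0),
                        ph_mean = 8, moisture_mean = 0.15)
    st <- generate_study(des, n_pairs = 0, seed = 900 + s)
    rec <- run_bef_pipeline(st$bacteria, st$fungi, st$samples,
                            include_beta = FALSE, min_n_assoc = 10)
    hits <- hits + (meta_correlation(rec, "neutral_r2", "r_alpha")$r > 0)
  }
  expect_gte(hits, 9)
})

test_that("end-to-end: planted anticorrelated association/function structure is recovered", {
  ok_sign <- 0; ok_rank <- 0
  for (s in 1:3) {
    des <- study_design(n_samples = 15, m_up = rep(0.5, 5),
                        pro_neg = c(0.1, 0.3, 0.5, 0.7, 0.9),
                        beta_mnc = c(1.0, 0.75, 0.5, 0.25, 0.0),
                        ph_mean = 8, moisture_mean = 0.15)
    des$m <- 0.5
    st <- generate_study(des, S = 250, n_reads = 5000, seed = 40 + s)
    rec <- run_bef_pipeline(st$bacteria, st$fungi, st$samples,
                            include_beta = FALSE, min_n_assoc = 10)
    mc <- meta_correlation(rec, "neg_bf_pro", "r_alpha")
    imp <- predictor_importance(rec, n_trees = 500, n_perm = 0, seed = 1)
    ok_sign <- ok_sign + (mc$r < 0)
    ok_rank <- ok_rank + (imp$predictor[1] == "neg_bf_pro")
  }
  expect_gte(ok_sign, 3)
  expect_gte(ok_rank, 2)
})
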