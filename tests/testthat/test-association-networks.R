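test_that("prevalence filter applies the strict boundary rule", {
  counts <- rbind(o1 = c(1L, 2L, 3L, 0L, 0L),   # 3/5 = 0.6, not > 0.6
                  o2 = c(1L, 2L, 3L, 4L, 0L),   # 4/5 kept
                  o3 = c(1L, 1L, 1L, 1L, 1L))
  colnames(counts) <- paste0("S", 1:5)
  x <- otu_table(counts, "bacteria")
  kept <- prevalence_filter(x, 0.60)
  expect_setequal(otu_ids(kept), c("o2", "o3"))
  kept2 <- prevalence_filter(x, 0.60, strict = FALSE)
  expect_setequal(otu_ids(kept2), c("o1", "o2", "o3"))
  expect_error(prevalence_filter(subset_table(x, otus = c("o1", "o2")), 0.9),
               "prevalence")

  # surviving set equals a brute-force scan on a simulated table
  meta <- simulate_metacommunity(300, "lognormal", list(sigma = 2), seed = 44)
  tab <- simulate_neutral_samples(meta, 25, 2000, 0.1, seed = 45)
  brute <- rownames(tab$counts)[apply(tab$counts, 1, function(r) mean(r >= 1) > 0.6)]
  expect_setequal(otu_ids(prevalence_filter(tab, 0.6)), brute)
})

test_that("spearman_edges handles exact monotone pairs and zero variance", {
  counts <- rbind(b1 = c(1L, 2L, 3L, 4L, 5L, 6L),
                  b2 = c(2L, 4L, 6L, 8L, 10L, 12L),
                  f1 = c(60L, 50L, 40L, 30L, 20L, 10L),
                  f2 = c(5L, 5L, 5L, 5L, 5L, 5L))
  colnames(counts) <- paste0("S", 1:6)
  x <- otu_table(counts, c(b1 = "bacteria", b2 = "bacteria",
                           f1 = "fungi", f2 = "fungi"))
  e <- spearman_edges(x, q_threshold = 0.05)
  ed <- e$edges
  expect_equal(ed$rho[ed$otu_a == "b1" & ed$otu_b == "b2"], 1)
  expect_equal(ed$rho[ed$otu_a == "b1" & ed$otu_b == "f1"], -1)
  expect_equal(ed$sign[ed$otu_a == "b1" & ed$otu_b == "f1"], "neg")
  # f2 has zero variance: its 3 pairs are skipped and tallied
  expect_equal(e$params$n_pairs_skipped, 3)
  expect_equal(e$params$n_pairs_tested, 3)
  expect_false(any(ed$otu_a == "f2" | ed$otu_b == "f2"))
  # canonical ordering and q threshold respected
  expect_true(all(ed$otu_a < ed$otu_b))
  expect_true(all(ed$q_fdr < 0.05))
})

test_that("t-approximation p is close to the exact permutation p at n=4", {
  x <- c(1, 2, 3, 4)
  y <- c(1.2, 2.1, 4.0, 3.1)   # rho = 0.8 against x
  rho_obs <- cor(x, y, method = "spearman")
  # enumerate all 24 orderings of y
  all_perm <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_perm(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  null_rho <- vapply(all_perm(y), function(py) cor(x, py, method = "spearman"), 1.0)
  p_exact <- mean(abs(null_rho) >= abs(rho_obs) - 1e-12)
  tt <- rho_obs * sqrt((4 - 2) / (1 - rho_obs^2))
  p_t <- 2 * pt(-abs(tt), df = 2)
  expect_lt(abs(p_t - p_exact), 0.15)

  counts <- rbind(a = c(10L, 20L, 30L, 41L), b = c(12L, 21L, 40L, 31L))
  colnames(counts) <- paste0("S", 1:4)
  suppressWarnings(e <- spearman_edges(otu_table(counts, "bacteria"),
                                       q_threshold = 1.01, fdr_method = "none"))
  expect_equal(e$edges$rho[1], rho_obs, tolerance = 1e-12)
  expect_equal(e$edges$p_raw[1], p_t, tolerance = 1e-9)
})

test_that("partition counts are additive and reproduce printed proportions", {
  # random edge fixture: counts in 'all' equal the sum of the partitions
  set.seed(99)
  meta <- simulate_metacommunity(60, "lognormal", list(sigma = 1), seed = 99)
  tab <- simulate_neutral_samples(meta, 30, 2000, 0.5, seed = 98)
  rel <- normalize_counts(prevalence_filter(tab, 0.6))
  e <- spearman_edges(rel, q_threshold = 0.5)
  s <- partition_and_count(e)
  expect_equal(s$neg[s$partition == "all"],
               sum(s$neg[s$partition != "all"]))
  expect_equal(s$pos[s$partition == "all"],
               sum(s$pos[s$partition != "all"]))
  expect_true(all(is.na(s$pro) | (s$pro >= 0 & s$pro <= 1)))

  # printed cross-kingdom counts for the agricultural whole profile
  expect_equal(round(26626 / (26626 + 36689), 3), 0.421)
})

test_that("summarize_groups emits one summary per group in Table-1 shape", {
  s <- tiny_study(seed = 2, n_samples = 12, S = 150)
  out <- suppressWarnings(
    summarize_groups(s$bacteria, s$fungi, s$samples, min_n = 10))
  expect_identical(colnames(out),
                   c("habitat", "layer", "partition", "neg", "pos", "pro"))
  expect_setequal(unique(out$layer), c("whole", "up", "down"))
  expect_true(all(is.na(out$pro) | abs(out$pro - out$neg / (out$neg + out$pos)) < 1e-12))

  # two habitats with identical data give identical summaries
  dup <- function(x, prefix) {
    counts <- x$counts
    colnames(counts) <- paste0(prefix, colnames(counts))
    otu_table(counts, x$kingdom)
  }
  b2 <- otu_table(cbind(dup(s$bacteria, "A_")$counts, dup(s$bacteria, "B_")$counts),
                  s$bacteria$kingdom)
  f2 <- otu_table(cbind(dup(s$fungi, "A_")$counts, dup(s$fungi, "B_")$counts),
                  s$fungi$kingdom)
  sm2 <- rbind(
    transform(s$samples, sample_id = paste0("A_", sample_id), habitat = "agricultural"),
    transform(s$samples, sample_id = paste0("B_", sample_id), habitat = "forest"))
  out2 <- suppressWarnings(
    summarize_groups(b2, f2, sm2, min_n = 10, scopes = "whole"))
  a_rows <- out2[out2$habitat == "agricultural", c("partition", "neg", "pos", "pro")]
  b_rows <- out2[out2$habitat == "forest", c("partition", "neg", "pos", "pro")]
  rownames(a_rows) <- rownames(b_rows) <- NULL
  expect_equal(a_rows, b_rows)
})

test_that("planted associations are recovered with the right sign and proportion", {
  hits <- numeric(5)
  pros <- numeric(5)
  for (s in 1:5) {
    meta <- simulate_metacommunity(200, "lognormal", list(sigma = 1.5), seed = 500 + s)
    tab <- simulate_neutral_samples(meta, 100, 10000, 0.3, seed = 600 + s)
    b <- subset_table(tab, otus = which(tab$kingdom == "bacteria"))
    f <- subset_table(tab, otus = which(tab$kingdom == "fungi"))
    pl <- plant_cross_kingdom_associations(b, f, n_neg = 20, n_pos = 20,
                                           strength = 4, seed = 700 + s)
    bb <- prevalence_filter(pl$bacteria)
    ff <- prevalence_filter(pl$fungi)
    rel <- combine_and_rescale(normalize_counts(bb), normalize_counts(ff))
    e <- spearman_edges(rel)
    ed <- e$edges[e$edges$kingdom_a != e$edges$kingdom_b, ]
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    hit <- match(key(pl$planted$otu_b, pl$planted$otu_f),
                 key(ed$otu_a, ed$otu_b))
    ok <- !is.na(hit) & ed$sign[hit] == pl$planted$sign
    hits[s] <- mean(ok)
    pros[s] <- mean(ed$sign == "neg")
  }
  expect_true(all(hits >= 0.8))
  # recovered cross-kingdom negative proportion near the planted 0.5
  expect_true(all(abs(pros - 0.5) <= 0.1))
})
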