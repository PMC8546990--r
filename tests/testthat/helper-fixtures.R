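# Small deterministic fixtures shared across test files.

# 3-OTU bacterial + 2-OTU fungal tables on 4 samples, hand-enterable counts.
tiny_tables <- function() {
  cb <- matrix(c(5L, 3L, 0L, 2L,
                 1L, 0L, 4L, 4L,
                 2L, 2L, 2L, 2L),
               nrow = 3, byrow = TRUE,
               dimnames = list(c("b1", "b2", "b3"), paste0("S", 1:4)))
  cf <- matrix(c(3L, 1L, 1L, 0L,
                 0L, 2L, 3L, 4L),
               nrow = 2, byrow = TRUE,
               dimnames = list(c("f1", "f2"), paste0("S", 1:4)))
  list(bacteria = otu_table(cb, "bacteria"),
       fungi = otu_table(cf, "fungi"))
}

# Simulated study small enough for unit tests, deterministic under seed.
tiny_study <- function(seed = 1, n_samples = 15, S = 120) {
  des <- study_design(n_samples = n_samples,
                      habitats = c("agricultural", "desert"),
                      m_up = c(0.5, 0.2), pro_neg = c(0.2, 0.8),
                      beta_mnc = c(1, 0), ph_mean = 8, moisture_mean = 0.15)
  generate_study(des, S = S, n_reads = 3000, n_pairs = 10, seed = seed)
}

# Independent from-scratch ANOSIM R statistic (rank formula), used as an
# oracle against the vegan-backed wrapper.
anosim_R_oracle <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  iu <- which(upper.tri(dm), arr.ind = TRUE)
  dv <- dm[upper.tri(dm)]
  rk <- rank(dv)
  within <- groups[iu[, 1]] == groups[iu[, 2]]
  M <- n * (n - 1) / 2
  (mean(rk[!within]) - mean(rk[within])) / (M / 2)
}
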