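## Synthetic two-kingdom communities with known ground truth: a metacommunity
## abundance pool, Sloan beta-multinomial neutral sampling, a niche-structured
## contrast, planted cross-kingdom associations, and nutrients linearly
## coupled to multidiversity.

#' Simulate a metacommunity abundance pool
#'
#' Draws `S` source-pool abundances from a lognormal or log-series species
#' abundance distribution, normalizes them to sum to 1, and assigns kingdoms:
#' the first `round(bacterial_fraction * S)` OTUs are bacterial (abundance
#' draws are exchangeable, so the assignment is arbitrary but deterministic).
#'
#' @param S Number of OTUs (>= 2).
#' @param distribution `"lognormal"` (param `sigma` >= 0, sdlog) or
#'   `"logseries"` (param `theta` in (0, 1)).
#' @param params Named list of distribution parameters.
#' @param bacterial_fraction Fraction of OTUs labelled bacterial (default
#'   0.7).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return List of class `metacommunity`: `p` (named relative abundances
#'   summing to 1), `kingdom`, `distribution`, `params`; raw (unnormalized)
#'   draws in attribute `"raw"`.
#' @export
simulate_metacommunity <- function(S, distribution = c("lognormal", "logseries"),
                                   params = list(), bacterial_fraction = 0.7,
                                   seed = NULL) {
  stopifnot(S >= 2)
  distribution <- match.arg(distribution)
  if (!is.null(seed)) set.seed(seed)
  if (distribution == "lognormal") {
    sigma <- if (is.null(params$sigma)) 1 else params$sigma
    if (sigma < 0) stop("lognormal sigma must be >= 0")
    raw <- if (sigma == 0) rep(1, S) else rlnorm(S, meanlog = 0, sdlog = sigma)
    params <- list(sigma = sigma)
  } else {
    theta <- if (is.null(params$theta)) 0.99 else params$theta
    if (theta <= 0 || theta >= 1) stop("logseries theta must be in (0, 1)")
    raw <- .rlogseries(S, theta)
    params <- list(theta = theta)
  }
  p <- raw / sum(raw)
  n_bact <- round(bacterial_fraction * S)
  kingdom <- c(rep("bacteria", n_bact), rep("fungi", S - n_bact))
  ids <- c(sprintf("B%04d", seq_len(n_bact)),
           sprintf("F%04d", seq_len(S - n_bact)))
  names(p) <- ids
  names(kingdom) <- ids
  structure(list(p = p, kingdom = kingdom, distribution = distribution,
                 params = params, bacterial_fraction = bacterial_fraction),
            class = "metacommunity", raw = raw)
}

## Log-series abundances by inverse-CDF sampling: P(k) proportional to
## theta^k / k, k = 1, 2, ...
.rlogseries <- function(S, theta) {
  kmax <- 10L
  repeat {
    k <- seq_len(kmax)
    pmf <- theta^k / k
    if (pmf[kmax] / sum(pmf) < 1e-12 || kmax > 1e7) break
    kmax <- kmax * 4L
  }
  cdf <- cumsum(pmf) / sum(pmf)
  findInterval(runif(S), cdf) + 1
}

#' Simulate neutrally assembled local communities
#'
#' Sloan's stationary model: for each sample, each OTU's local relative
#' abundance is drawn from `Beta(N m p_i, N m (1 - p_i))` with `N = n_reads`,
#' the draws are renormalized, and `n_reads` reads are drawn multinomially,
#' so every sample column sums to exactly `n_reads`. The local abundance has
#' mean `p_i` and variance `p_i (1 - p_i) / (N m + 1)`: smaller `m` means
#' stronger dispersal limitation and more over-dispersed occupancy.
#'
#' @param meta A `metacommunity`.
#' @param n_samples Number of samples (0 gives an empty 0-column table).
#' @param n_reads Reads per sample (community size N).
#' @param m Migration rate in (0, 1].
#' @param seed Integer seed, or `NULL`.
#' @param sample_ids Optional sample id vector (default `S1..Sn`).
#' @return An `otu_table`.
#' @export
simulate_neutral_samples <- function(meta, n_samples, n_reads, m, seed = NULL,
                                     sample_ids = NULL) {
  stopifnot(inherits(meta, "metacommunity"))
  if (m <= 0 || m > 1) stop("m must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  S <- length(meta$p)
  a <- n_reads * m * meta$p
  b <- n_reads * m * (1 - meta$p)
  if (any(a <= 0) || any(b <= 0)) stop("degenerate beta parameters")
  counts <- matrix(0L, nrow = S, ncol = n_samples)
  if (n_samples > 0) {
    for (s in seq_len(n_samples)) {
      q <- rbeta(S, a, b)
      tries <- 0L
      while (sum(q) == 0 && tries < 100L) {  # numeric underflow guard
        q <- rbeta(S, a, b)
        tries <- tries + 1L
      }
      if (sum(q) == 0) stop("beta draws underflowed to zero for every OTU")
      counts[, s] <- rmultinom(1L, size = n_reads, prob = q)
    }
  }
  rownames(counts) <- names(meta$p)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(n_samples))
  colnames(counts) <- sample_ids
  otu_table(counts, meta$kingdom)
}

#' Simulate niche-structured local communities
#'
#' The deterministic contrast to [simulate_neutral_samples()]: each OTU gets
#' a niche optimum on a 1-D environment (uniform on \[0, 1\]), each sample an
#' environmental position, and expected abundances are
#' `p_i * exp(-(env - optimum_i)^2 / (2 breadth^2))`, renormalized and
#' sampled multinomially. Narrow `breadth` means strong environmental
#' structuring; as `breadth` grows the expected composition tends to the
#' metacommunity (the neutral marginal mean).
#'
#' @param meta A `metacommunity`.
#' @param n_samples Number of samples.
#' @param n_reads Reads per sample.
#' @param breadth Niche breadth (> 0) on the environmental axis.
#' @param seed Integer seed, or `NULL`.
#' @param env Optional per-sample environment values (default uniform draws).
#' @param optima Optional per-OTU niche optima (default uniform draws).
#' @param sample_ids Optional sample id vector.
#' @return An `otu_table` with attributes `"env"` and `"optima"`.
#' @export
simulate_niche_samples <- function(meta, n_samples, n_reads, breadth,
                                   seed = NULL, env = NULL, optima = NULL,
                                   sample_ids = NULL) {
  stopifnot(inherits(meta, "metacommunity"))
  if (breadth <= 0) stop("niche breadth must be positive")
  if (!is.null(seed)) set.seed(seed)
  S <- length(meta$p)
  if (is.null(env)) env <- runif(n_samples)
  if (is.null(optima)) optima <- runif(S)
  counts <- matrix(0L, nrow = S, ncol = n_samples)
  for (s in seq_len(n_samples)) {
    w <- meta$p * exp(-(env[s] - optima)^2 / (2 * breadth^2))
    counts[, s] <- rmultinom(1L, size = n_reads, prob = w)
  }
  rownames(counts) <- names(meta$p)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(n_samples))
  colnames(counts) <- sample_ids
  out <- otu_table(counts, meta$kingdom)
  attr(out, "env") <- setNames(env, sample_ids)
  attr(out, "optima") <- setNames(optima, names(meta$p))
  out
}

## Round non-negative reals to integers preserving the target total
## (largest-remainder rule, ties broken by index).
.round_preserve_sum <- function(x, total) {
  if (total == 0 || sum(x) == 0) return(integer(length(x)))
  scaled <- x * total / sum(x)
  fl <- floor(scaled)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0) {
    idx <- order(scaled - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

#' Plant cross-kingdom pairwise associations
#'
#' Couples disjoint (bacterial, fungal) OTU pairs through a shared
#' per-sample latent factor: pair counts are multiplied by
#' `exp(+strength (z - 0.5))` for the bacterial member and
#' `exp(+/- strength (z - 0.5))` for the fungal member (`+` for a planted
#' positive, `-` for a planted negative association), with `z` uniform per
#' sample and per pair. The multiplicative (log-additive) form keeps expected
#' counts positive; Spearman associations only need the induced monotone
#' coupling. Columns are re-integerized and rescaled so each sample keeps its
#' original read total. Pairs are drawn among prevalent OTUs so downstream
#' prevalence filtering retains them.
#'
#' @param bacteria,fungi `otu_table` objects on the same samples.
#' @param n_neg,n_pos Numbers of negative / positive pairs to plant.
#' @param strength Coupling strength (>= 0; 0 leaves the tables unchanged).
#' @param seed Integer seed, or `NULL`.
#' @param prevalence Minimum detection fraction for eligible OTUs.
#' @return List: `bacteria`, `fungi` (modified tables), `planted`
#'   (data.frame `otu_b`, `otu_f`, `sign`).
#' @export
plant_cross_kingdom_associations <- function(bacteria, fungi, n_neg, n_pos,
                                             strength, seed = NULL,
                                             prevalence = 0.6) {
  stopifnot(inherits(bacteria, "otu_table"), inherits(fungi, "otu_table"))
  if (strength < 0) stop("strength must be >= 0")
  if (!identical(sample_ids(bacteria), sample_ids(fungi))) {
    fungi <- subset_table(fungi, samples = sample_ids(bacteria))
  }
  if (!is.null(seed)) set.seed(seed)
  n_pairs <- n_neg + n_pos
  n <- ncol(bacteria$counts)
  prev_b <- rownames(bacteria$counts)[rowMeans(bacteria$counts >= 1) >= prevalence]
  prev_f <- rownames(fungi$counts)[rowMeans(fungi$counts >= 1) >= prevalence]
  if (n_pairs > min(length(prev_b), length(prev_f))) {
    stop("not enough prevalent OTUs for ", n_pairs, " disjoint pairs (",
         length(prev_b), " bacterial, ", length(prev_f), " fungal available)")
  }
  sel_b <- sample(prev_b, n_pairs)
  sel_f <- sample(prev_f, n_pairs)
  signs <- sample(rep(c("neg", "pos"), c(n_neg, n_pos)))

  cb <- bacteria$counts * 1.0
  cf <- fungi$counts * 1.0
  tot_b <- colSums(bacteria$counts)
  tot_f <- colSums(fungi$counts)
  for (k in seq_len(n_pairs)) {
    z <- runif(n) - 0.5
    cb[sel_b[k], ] <- cb[sel_b[k], ] * exp(strength * z)
    sgn <- if (signs[k] == "neg") -1 else 1
    cf[sel_f[k], ] <- cf[sel_f[k], ] * exp(sgn * strength * z)
  }
  for (s in seq_len(n)) {
    cb[, s] <- .round_preserve_sum(cb[, s], tot_b[s])
    cf[, s] <- .round_preserve_sum(cf[, s], tot_f[s])
  }
  list(bacteria = otu_table(cb, bacteria$kingdom),
       fungi = otu_table(cf, fungi$kingdom),
       planted = data.frame(otu_b = sel_b, otu_f = sel_f, sign = signs,
                            strength = strength, stringsAsFactors = FALSE))
}

#' Simulate nutrient variables coupled to multidiversity
#'
#' Each of the eight nutrient variables is
#' `baseline_k + beta_mnc * multidiv + Normal(0, sigma)`: a linear
#' diversity-to-function coupling with effect size `beta_mnc` shared across
#' nutrients and independent noise. With `sigma = 0` and `beta_mnc > 0` the
#' MNC is an exact affine image of multidiversity (Pearson r = 1).
#'
#' @param multidiv Named per-sample multidiversity values.
#' @param beta_mnc Effect size (slope) of multidiversity on every nutrient.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed, or `NULL`.
#' @param baselines Named baseline levels per nutrient (plausible field
#'   magnitudes; min-max standardization absorbs them).
#' @return Numeric matrix, samples x 8 nutrient variables.
#' @export
simulate_nutrients <- function(multidiv, beta_mnc, sigma, seed = NULL,
                               baselines = c(SOC = 10, DOC = 0.5, MBC = 0.3,
                                             NO3 = 5, NH4 = 2, MBN = 0.05,
                                             AP = 8, AK = 150)) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  vars <- nutrient_vars()
  n <- length(multidiv)
  out <- matrix(NA_real_, nrow = n, ncol = length(vars),
                dimnames = list(names(multidiv), vars))
  for (v in vars) {
    out[, v] <- baselines[[v]] + beta_mnc * multidiv + rnorm(n, 0, sigma)
  }
  out
}

#' Default cross-habitat study design
#'
#' One row per habitat x layer group with the generator's per-group
#' conditions: migration rate `m` (surface layers less dispersal limited than
#' subsurface), planted negative cross-kingdom association proportion
#' `pro_neg`, diversity-to-function effect size `beta_mnc` (anticorrelated
#' with `pro_neg` across habitats), and habitat-level pH / moisture means.
#'
#' @param n_samples Samples per habitat x layer group (default 25, i.e. a
#'   250-sample study).
#' @param habitats Habitat names.
#' @param m_up Surface-layer migration rate per habitat.
#' @param pro_neg Planted negative proportion per habitat (planting is done
#'   per habitat across both layers, so both layer rows share it).
#' @param beta_mnc Nutrient coupling effect size per habitat.
#' @param ph_mean,moisture_mean Habitat-level pH and moisture means; pass a
#'   constant to make them uninformative about the habitat.
#' @return Data frame with one row per habitat x layer.
#' @export
study_design <- function(n_samples = 25,
                         habitats = .default_habitats,
                         m_up = c(0.50, 0.35, 0.30, 0.15, 0.10),
                         pro_neg = c(0.42, 0.40, 0.31, 0.56, 0.55),
                         beta_mnc = c(1.0, 0.8, 0.6, 0.15, 0.0),
                         ph_mean = c(8.0, 7.6, 8.2, 8.4, 8.6),
                         moisture_mean = c(0.18, 0.15, 0.25, 0.08, 0.03)) {
  stopifnot(length(habitats) == length(m_up),
            length(habitats) == length(pro_neg),
            length(habitats) == length(beta_mnc))
  ph <- rep_len(ph_mean, length(habitats))
  moist <- rep_len(moisture_mean, length(habitats))
  up <- data.frame(habitat = habitats, layer = "up", n_samples = n_samples,
                   m = m_up, pro_neg = pro_neg, beta_mnc = beta_mnc,
                   ph_mean = ph, moisture_mean = moist,
                   stringsAsFactors = FALSE)
  down <- up
  down$layer <- "down"
  down$m <- pmax(0.6 * up$m, 1e-3)
  rbind(up, down)
}

#' Generate a full synthetic study with ground truth
#'
#' One call yields a complete two-kingdom study emulating a cross-habitat,
#' two-soil-layer survey: per habitat x layer group, neutrally assembled
#' samples at the group's migration rate from a shared metacommunity;
#' per habitat, planted cross-kingdom associations across both layers at the
#' habitat's negative proportion (so whole-profile and per-layer networks
#' see the same pairs); and nutrient variables coupled to the realized
#' multidiversity (standardized across all samples) at the group's effect
#' size. The returned `truth` record carries every generator parameter for
#' end-to-end recovery tests.
#'
#' @param design Study design data.frame (see [study_design()]): columns
#'   `habitat`, `layer`, `n_samples`, `m`, `pro_neg`, `beta_mnc`, `ph_mean`,
#'   `moisture_mean`. At least 2 groups.
#' @param S Metacommunity size (number of OTUs).
#' @param bacterial_fraction Fraction of bacterial OTUs.
#' @param n_reads Reads per sample.
#' @param distribution,dist_params Metacommunity abundance distribution.
#' @param n_pairs Planted cross-kingdom pairs per group (split into negative
#'   and positive by the group's `pro_neg`).
#' @param strength Planting coupling strength.
#' @param sigma_nutrient Nutrient noise standard deviation.
#' @param seed Integer seed; the single source of randomness.
#' @return List: `bacteria`, `fungi` (`otu_table`s), `samples` (sample
#'   frame), `truth` (list with `seed`, `design` including planted counts,
#'   `planted` pair lists per group, `S`, `n_reads`, `strength`,
#'   `sigma_nutrient`).
#' @export
generate_study <- function(design = study_design(), S = 400,
                           bacterial_fraction = 0.7, n_reads = 10000,
                           distribution = "lognormal",
                           dist_params = list(sigma = 1.5),
                           n_pairs = 40, strength = 3, sigma_nutrient = 0.3,
                           seed = 1) {
  required <- c("habitat", "layer", "n_samples", "m", "pro_neg", "beta_mnc",
                "ph_mean", "moisture_mean")
  missing <- setdiff(required, colnames(design))
  if (length(missing)) stop("design missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(design) < 2L) stop("need at least 2 groups")
  if (any(design$pro_neg < 0 | design$pro_neg > 1)) stop("pro_neg must be in [0, 1]")
  if (any(design$m <= 0 | design$m > 1)) stop("m must be in (0, 1]")
  set.seed(seed)
  meta <- simulate_metacommunity(S, distribution, dist_params,
                                 bacterial_fraction, seed = NULL)

  sample_rows <- list(); planted <- list()
  design$n_neg <- as.integer(round(design$pro_neg * n_pairs))
  design$n_pos <- as.integer(n_pairs - design$n_neg)
  hab_bact <- list(); hab_fung <- list()

  for (hab in unique(design$habitat)) {
    rows <- design[design$habitat == hab, , drop = FALSE]
    b_blocks <- list(); f_blocks <- list()
    for (g in seq_len(nrow(rows))) {
      row <- rows[g, ]
      prefix <- sprintf("%s_%s", substr(row$habitat, 1, 3), row$layer)
      ids <- sprintf("%s_%02d", prefix, seq_len(row$n_samples))
      tab <- simulate_neutral_samples(meta, row$n_samples, n_reads, row$m,
                                      seed = NULL, sample_ids = ids)
      b_blocks[[g]] <- tab$counts[meta$kingdom == "bacteria", , drop = FALSE]
      f_blocks[[g]] <- tab$counts[meta$kingdom == "fungi", , drop = FALSE]
      sample_rows[[paste(hab, row$layer)]] <- data.frame(
        sample_id = ids, habitat = row$habitat, layer = row$layer,
        site = sprintf("site_%s_%02d", substr(row$habitat, 1, 3),
                       ceiling(seq_len(row$n_samples) / 2)),
        pH = rnorm(row$n_samples, row$ph_mean, 0.2),
        moisture = pmax(0.005, rnorm(row$n_samples, row$moisture_mean, 0.03)),
        stringsAsFactors = FALSE)
    }
    b <- otu_table(do.call(cbind, b_blocks),
                   meta$kingdom[meta$kingdom == "bacteria"])
    f <- otu_table(do.call(cbind, f_blocks),
                   meta$kingdom[meta$kingdom == "fungi"])
    ## Associations are a habitat-level property: the same pairs are coupled
    ## in both soil layers so whole-profile and per-layer networks agree.
    if (n_pairs > 0 && strength > 0) {
      pl <- plant_cross_kingdom_associations(b, f, rows$n_neg[1L],
                                             rows$n_pos[1L], strength,
                                             seed = NULL)
      b <- pl$bacteria; f <- pl$fungi
      planted[[hab]] <- pl$planted
    }
    hab_bact[[hab]] <- b$counts
    hab_fung[[hab]] <- f$counts
  }

  bacteria <- otu_table(do.call(cbind, hab_bact),
                        meta$kingdom[meta$kingdom == "bacteria"])
  fungi <- otu_table(do.call(cbind, hab_fung),
                     meta$kingdom[meta$kingdom == "fungi"])
  samples <- do.call(rbind, sample_rows)

  ## Realized diversity across the whole study, then group-wise nutrient
  ## coupling at the group's effect size.
  h <- shannon(normalize_counts(bacteria, "tss"))
  r <- richness(fungi)
  md <- multidiversity(h, r)
  nut <- matrix(NA_real_, nrow = nrow(samples), ncol = 8,
                dimnames = list(samples$sample_id, nutrient_vars()))
  for (g in seq_len(nrow(design))) {
    row <- design[g, ]
    idx <- samples$habitat == row$habitat & samples$layer == row$layer
    nut[idx, ] <- simulate_nutrients(md[samples$sample_id[idx]],
                                     row$beta_mnc, sigma_nutrient,
                                     seed = NULL)
  }
  samples <- cbind(samples, as.data.frame(nut))
  rownames(samples) <- NULL

  list(bacteria = bacteria, fungi = fungi, samples = samples,
       truth = list(seed = seed, design = design, planted = planted,
                    S = S, n_reads = n_reads, n_pairs = n_pairs,
                    strength = strength, sigma_nutrient = sigma_nutrient,
                    multidiversity = md))
}
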