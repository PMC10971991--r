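# Shared fixture generators. Everything is built in code from explicit
# seeds; no data files.

# Three-class cohort with two strong complementary markers (M001 separates
# class B, M002 separates class C) among noise columns.
two_marker_config <- function(seed, n_per_group = c(15, 10, 8),
                              n_metabolites = 6, shift = 8,
                              noise_sigma = 0.2) {
  synthetic_config(
    n_per_group = n_per_group, n_metabolites = n_metabolites,
    class_names = c("A", "B", "C"),
    markers = list(list(index = 1, shift = c(1, shift, 1)),
                   list(index = 2, shift = c(1, 1, shift))),
    noise_sigma = noise_sigma, seed = seed)
}

# Cohort whose classes are separable only through the product of the first
# two metabolites: moderate fold-change, tight log-noise (see the methods
# vignette for why large ratios would break raw-scale pooled covariance).
product_only_config <- function(seed, n_per_group = c(31, 8, 7),
                                n_metabolites = 4) {
  synthetic_config(
    n_per_group = n_per_group, n_metabolites = n_metabolites,
    class_names = c("Control", "Glaucoma", "Diabetes"),
    nonlinear = list(pair = c(1, 2), shift = c(1, 4, 1 / 4),
                     latent_sd = 3),
    noise_sigma = 0.08, seed = seed)
}

# Pure-noise cohort with the study's class layout.
null_config <- function(seed, n_metabolites = 1) {
  synthetic_config(n_per_group = c(31, 8, 7),
                   n_metabolites = n_metabolites,
                   class_names = c("Control", "Glaucoma", "Diabetes"),
                   noise_sigma = 0.5, seed = seed)
}

# Random small instance for oracle-equivalence checks: K=3 classes,
# n <= 30, p <= 4, well-conditioned Gaussian features.
random_instance <- function(seed) {
  set.seed(seed)
  K <- 3
  p <- sample(1:4, 1)
  nk <- sample(3:10, K, replace = TRUE)
  g <- factor(rep(LETTERS[1:K], nk))
  mu <- matrix(rnorm(K * p, sd = 2), K, p)
  X <- mu[as.integer(g), , drop = FALSE] + matrix(rnorm(sum(nk) * p),
                                                  sum(nk), p)
  colnames(X) <- paste0("V", seq_len(p))
  list(X = X, g = g)
}

baseline_accuracy <- function(n_per_group) max(n_per_group) / sum(n_per_group)

# Reproduce the generator's per-metabolite log-baselines from its seed
# (first draw in the generation sequence), without touching the caller's
# RNG stream.
with_seed_mu <- function(cfg) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  runif(cfg$n_metabolites, cfg$baseline_log_range[1],
        cfg$baseline_log_range[2])
}
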