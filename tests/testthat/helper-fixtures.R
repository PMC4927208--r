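# Shared fixtures, built in code at test time.

# one class per (temporal, AU-component) combination, distinguished by a
# single elevated coefficient — separating all classes requires every
# component of the planted order
onehot_class_means <- function(p, l, lo = 0.4, hi = 1.8) {
  out <- list()
  for (pp in seq_len(p)) {
    for (ll in seq_len(l)) {
      m <- matrix(lo, p, l)
      m[pp, ll] <- hi
      out[[paste0("c", pp, "_", ll)]] <- m
    }
  }
  out
}

# balanced two-class table whose features carry no class information
chance_table <- function(n_per_class = 200L, d = 10L, seed = 1L) {
  set.seed(seed)
  x <- matrix(abs(rnorm(2L * n_per_class * d)), ncol = d)
  colnames(x) <- paste0("f", seq_len(d))
  out <- tibble::as_tibble(x)
  out$.label <- rep(c("a", "b"), each = n_per_class)
  out
}

# small noiseless planted dataset at the study-like (P = 2, L = 3) structure
recovery_fixture <- function(n_per_class = 30L, s = 8L, seed = 7L,
                             coeff_noise = 0.5) {
  pm <- planted_study_model(p = 2L, l = 3L, s = s,
                            coeff_noise_scale = coeff_noise)
  list(pm = pm, data = simulate_planted(pm, n_per_class, seed = seed))
}

# direct two-class coefficient table from planted gaussian features
two_class_table <- function(mu_a, mu_b, n = 60L, sd = 1, seed = 1L) {
  set.seed(seed)
  d <- length(mu_a)
  x <- rbind(
    matrix(rnorm(n * d, rep(mu_a, each = n), sd), n, d),
    matrix(rnorm(n * d, rep(mu_b, each = n), sd), n, d))
  colnames(x) <- paste0("f", seq_len(d))
  out <- tibble::as_tibble(x)
  out$.label <- rep(c("a", "b"), each = n)
  out
}
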