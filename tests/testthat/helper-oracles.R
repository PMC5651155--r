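# Independent oracles and fixture builders. The oracles deliberately use
# direct summation / exhaustive enumeration, never the package's fast paths.

# direct-summation implementation of the eight window statistics
oracle_features <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  sigma <- sqrt(sum((x - mu)^2) / (n - 1))
  s <- sort(x)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  if (n %% 2 == 0) {
    lower <- s[1:(n / 2)]
    upper <- s[(n / 2 + 1):n]
  } else {
    lower <- s[1:((n - 1) / 2)]
    upper <- s[((n + 3) / 2):n]
  }
  kur <- if (sigma == 0) 0 else sum((x - mu)^4) / ((n - 1) * sigma^4)
  ske <- if (sigma == 0) 0 else sum((x - mu)^3) / ((n - 1) * sigma^3)
  c(X1 = max(x), X2 = min(x), X3 = mu, X4 = sigma, X5 = med,
    X6 = stats::median(upper) - stats::median(lower), X7 = kur, X8 = ske)
}

# exhaustive sort-and-vote KNN oracle (distance ties by insertion order,
# vote ties by the single nearest reference's label)
oracle_knn <- function(values, labels, k, query) {
  df <- data.frame(d = abs(query - values), i = seq_along(values),
                   lab = labels)
  df <- df[order(df$d, df$i), ]
  votes <- df$lab[1:k]
  n_spike <- sum(votes == "spike")
  if (2 * n_spike > k) "spike"
  else if (2 * n_spike < k) "nonspike"
  else df$lab[1]
}

# brute-force enumeration of full windows of length n every `step` samples
brute_starts <- function(L, n, step) {
  out <- integer(0)
  s <- 0L
  while (s + n <= L) {
    out <- c(out, s)
    s <- s + step
  }
  out
}

# feature table where only X4 separates the classes
x4_feature_table <- function(n_per_class, mu_spike = 3, mu_nonspike = 1,
                             sd = 0.1) {
  n <- 2L * n_per_class
  df <- as.data.frame(matrix(rnorm(n * 8), n, 8,
                             dimnames = list(NULL, paste0("X", 1:8))))
  df$label <- rep(c("spike", "nonspike"), each = n_per_class)
  df$X4 <- rnorm(n, ifelse(df$label == "spike", mu_spike, mu_nonspike), sd)
  df
}

x4_context <- function(n_per_class = 60, k = 15, ...) {
  fitness_context(x4_feature_table(n_per_class, ...),
                  x4_feature_table(n_per_class, ...), k = k)
}

# named list of simulated "patients"
sim_patients <- function(ids, duration_s, snr, seed0, spike_rate = 6) {
  stats::setNames(lapply(seq_along(ids), function(i)
    simulate_recording(sim_config(duration_s = duration_s, snr = snr,
                                  spike_rate = spike_rate,
                                  rng_seed = seed0 + i))), ids)
}

# one full three-stage run on simulated data; returns the pipeline result
run_sim_pipeline <- function(seed, snr, n_train = 8, n_holdout = 4,
                             train_s = 40, holdout_s = 75,
                             gp_generations = 100) {
  train <- sim_patients(sprintf("tr%02d", seq_len(n_train)), train_s, snr,
                        seed0 = seed * 1000L)
  holdout <- sim_patients(sprintf("ho%02d", seq_len(n_holdout)), holdout_s,
                          snr, seed0 = seed * 1000L + 500L)
  cfg <- experiment_config(gp = gp_config(n_generations = gp_generations,
                                          rng_seed = seed + 1L),
                           balance_seed = seed)
  run_pipeline(train, holdout, cfg, seed = seed)
}
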