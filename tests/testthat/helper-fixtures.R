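# shared fixtures built in code

# small trial table with known parameter spread
toy_trials <- function(n = 20, seed = 7) {
  withr::with_seed(seed, tibble::tibble(
    speed = runif(n, 1.5, 3.5),
    segment_fraction = runif(n, 0.5, 0.9),
    deceleration_increment = runif(n, 0.8, 3.2)
  ))
}

# noiseless ratings from known control-model parameters on a session
noiseless_session <- function(gamma = 0.35,
                              betas = c(deceleration = 2, segment_size = -2,
                                        speed = -3),
                              intercept = 50, study = "study1", seed = 5) {
  sched <- build_session(study, seed = seed)
  X <- prepare_regressors(sched$trials)
  pred <- predict_ratings(smooth_regressors(X, gamma), betas, intercept)
  idx <- sched$probes$after_trial[sched$probes$kind == "control"]
  y <- rep(NA_real_, nrow(X))
  y[idx] <- pred[idx]
  list(sched = sched, X = X, y = y, idx = idx, pred = pred,
       truth = list(gamma = gamma, betas = betas, intercept = intercept))
}

# brute-force two-way ANOVA mean squares by direct summation (ICC oracle)
anova_ms_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(m[i, ]) - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(m[, j]) - grand)^2
  sst <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (m[i, j] - grand)^2
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = (sst - ssr - ssc) / ((n - 1) * (k - 1)))
}

# brute-force BH step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m / i * p[ord[i]])
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}
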