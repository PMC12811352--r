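# Brute-force oracles kept deliberately naive and independent of the
# package's recursive implementations.

# total likelihood by explicit enumeration of all K^T state paths
enum_forward_lik <- function(P, Gamma, delta) {
  Tn <- nrow(P); K <- ncol(P)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- delta[s[1]] * P[1, s[1]]
    if (Tn > 1) for (t in 2:Tn) pr <- pr * Gamma[s[t - 1], s[t]] * P[t, s[t]]
    tot <- tot + pr
  }
  unname(tot)
}

# most probable path by enumeration (returns indices)
enum_viterbi <- function(P, Gamma, delta) {
  Tn <- nrow(P); K <- ncol(P)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- delta[s[1]] * P[1, s[1]]
    if (Tn > 1) for (t in 2:Tn) pr <- pr * Gamma[s[t - 1], s[t]] * P[t, s[t]]
    if (pr > best) { best <- pr; best_path <- s }
  }
  list(path = as.integer(unname(best_path)), lik = unname(best))
}

# smoothed marginal state probabilities by enumeration
enum_marginals <- function(P, Gamma, delta) {
  Tn <- nrow(P); K <- ncol(P)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  M <- matrix(0, Tn, K)
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- delta[s[1]] * P[1, s[1]]
    if (Tn > 1) for (t in 2:Tn) pr <- pr * Gamma[s[t - 1], s[t]] * P[t, s[t]]
    for (t in seq_len(Tn)) M[t, s[t]] <- M[t, s[t]] + pr
  }
  M / rowSums(M)
}

# random stochastic matrix
rand_stochastic <- function(K) {
  G <- matrix(rexp(K * K), K)
  G / rowSums(G)
}

# random movement-only instance: intervals plus parameters (K <= 3)
rand_hmm_instance <- function(Tn, K, with_known = FALSE, with_na = TRUE) {
  labels <- arsHMM::state_labels(K)
  mu <- sort(runif(K, 0.1, 8))
  sigma <- mu * runif(K, 0.3, 1.2)
  kappa <- runif(K, 0, 0.9)
  params <- arsHMM::hmm_params(labels, mu, sigma, kappa,
                               Gamma = rand_stochastic(K),
                               delta = {
                                 d <- rexp(K); d / sum(d)
                               })
  step <- rgamma(Tn, 2, 1)
  angle <- runif(Tn, -pi, pi)
  if (with_na) {
    step[runif(Tn) < 0.15] <- NA
    angle[runif(Tn) < 0.15] <- NA
  }
  known <- rep("free", Tn)
  if (with_known) {
    pick <- runif(Tn) < 0.3
    known[pick] <- sample(labels, sum(pick), replace = TRUE)
  }
  intervals <- data.frame(id = "a", step = step, angle = angle,
                          known = known, stringsAsFactors = FALSE)
  list(intervals = intervals, params = params)
}

# simple independent linear interpolation at a single time
lerp_at <- function(tt, xx, yy, t0) {
  i <- max(which(tt <= t0)); j <- min(which(tt >= t0))
  if (i == j) return(c(xx[i], yy[i]))
  w <- (t0 - tt[i]) / (tt[j] - tt[i])
  c(xx[i] + w * (xx[j] - xx[i]), yy[i] + w * (yy[j] - yy[i]))
}
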