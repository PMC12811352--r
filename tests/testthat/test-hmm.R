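test_that("forward likelihood equals brute-force path enumeration", {
  set.seed(101)
  for (rep in 1:25) {
    K <- sample(2:3, 1)
    inst <- rand_hmm_instance(sample(3:6, 1), K, with_known = (K == 3))
    P <- emission_matrix(inst$intervals, inst$params)
    oracle <- enum_forward_lik(P, inst$params$Gamma, inst$params$delta)
    ll <- forward_loglik(inst$intervals, inst$params)
    expect_equal(ll, log(oracle), tolerance = 1e-10)
  }
})

test_that("fast C-level likelihood agrees with the matrix-based recursion", {
  # two independent emission implementations must coincide
  set.seed(55)
  cfg <- simulation_config(3, 300, species = "grey",
                           movement_states_only = FALSE, gap_rate = 0.02,
                           seed = 19)
  iv <- tracks_to_intervals(simulate_hmm_tracks(cfg))
  p <- species_profile("grey", 5)
  d <- arsHMM:::prepare_hmm_data(iv, p)
  nll <- arsHMM:::C_nll(d$step, d$log_step, d$cos_angle, d$known,
                        d$seq_start, arsHMM:::full_par(p$mu, p),
                        arsHMM:::full_par(p$sigma, p),
                        arsHMM:::full_par(p$kappa, p),
                        arsHMM:::full_par(p$zeromass, p),
                        p$emits, p$n_move, p$Gamma, p$delta)
  expect_equal(-nll, forward_loglik(iv, p), tolerance = 1e-8)
})

test_that("degenerate single-interval chains reduce to the emission density", {
  p <- hmm_params(state_labels(3), mu = c(0.1, 2, 6),
                  sigma = c(0.1, 1.5, 2), kappa = c(0.1, 0.5, 0.8),
                  Gamma = rand_stochastic(3), delta = c(1, 0, 0))
  iv <- data.frame(id = "a", step = 0.25, angle = 0.3, known = "fARS")
  ll <- forward_loglik(iv, p)
  expect_equal(ll, log(step_density(0.25, 0.1, 0.1) *
                         angle_density(0.3, 0.1)), tolerance = 1e-12)
})

test_that("likelihood is invariant to state relabelling", {
  set.seed(33)
  inst <- rand_hmm_instance(40, 3)
  perm <- c(2, 3, 1)
  pp <- inst$params
  permuted <- hmm_params(pp$states, unname(pp$mu[perm]),
                         unname(pp$sigma[perm]), unname(pp$kappa[perm]),
                         unname(pp$zeromass[perm]),
                         pp$Gamma[perm, perm], unname(pp$delta[perm]))
  expect_equal(forward_loglik(inst$intervals, inst$params),
               forward_loglik(inst$intervals, permuted), tolerance = 1e-10)
})

test_that("masking an interval to a known state cannot raise the likelihood", {
  set.seed(44)
  for (rep in 1:10) {
    inst <- rand_hmm_instance(30, 3, with_known = FALSE)
    free_ll <- forward_loglik(inst$intervals, inst$params)
    iv2 <- inst$intervals
    k <- sample(nrow(iv2), 1)
    iv2$known[k] <- sample(inst$params$states, 1)
    masked_ll <- forward_loglik(iv2, inst$params)
    expect_lte(masked_ll, free_ll + 1e-10)
  }
})

test_that("masking every interval to the truth beats other single paths", {
  cfg <- simulation_config(1, 200, species = "grey", seed = 61)
  iv <- tracks_to_intervals(simulate_hmm_tracks(cfg))
  p <- species_profile("grey", 3)
  iv_true <- iv; iv_true$known <- iv$state
  ll_true <- forward_loglik(iv_true, p)
  for (rep in 1:5) {
    iv_alt <- iv
    iv_alt$known <- sample(p$states, nrow(iv), replace = TRUE)
    expect_lte(forward_loglik(iv_alt, p), ll_true)
  }
})

test_that("Viterbi equals brute-force argmax over all paths", {
  set.seed(202)
  for (rep in 1:25) {
    K <- sample(2:3, 1)
    inst <- rand_hmm_instance(sample(4:8, 1), K, with_known = (rep %% 2 == 0))
    P <- emission_matrix(inst$intervals, inst$params)
    o <- enum_viterbi(P, inst$params$Gamma, inst$params$delta)
    v <- viterbi_decode(inst$intervals, inst$params)
    expect_equal(match(v, inst$params$states), o$path)
  }
})

test_that("fully constrained decoding returns the known codes", {
  set.seed(3)
  inst <- rand_hmm_instance(25, 3)
  inst$intervals$known <- sample(inst$params$states, 25, replace = TRUE)
  expect_equal(viterbi_decode(inst$intervals, inst$params),
               inst$intervals$known)
})

test_that("Viterbi recovers well-separated simulated movement states", {
  cfg <- simulation_config(4, 500, species = "grey", seed = 83)
  iv <- tracks_to_intervals(simulate_hmm_tracks(cfg))
  v <- viterbi_decode(iv, species_profile("grey", 3))
  expect_gt(mean(v == iv$state), 0.9)
})

test_that("local state probabilities match enumeration marginals", {
  set.seed(303)
  for (rep in 1:10) {
    inst <- rand_hmm_instance(6, 3, with_known = (rep %% 2 == 0))
    P <- emission_matrix(inst$intervals, inst$params)
    M <- enum_marginals(P, inst$params$Gamma, inst$params$delta)
    pr <- local_state_probs(inst$intervals, inst$params)
    expect_equal(unname(pr), M, tolerance = 1e-10)
    expect_equal(rowSums(pr), rep(1, 6), tolerance = 1e-8)
  }
})

test_that("known-state intervals get indicator probability vectors", {
  set.seed(17)
  inst <- rand_hmm_instance(30, 3, with_known = TRUE)
  pr <- local_state_probs(inst$intervals, inst$params)
  kn <- inst$intervals$known != "free"
  idx <- match(inst$intervals$known[kn], inst$params$states)
  expect_equal(pr[cbind(which(kn), idx)], rep(1, sum(kn)))
})

test_that("single-state fits recover moment-level estimates", {
  set.seed(71)
  p <- hmm_params("S1", mu = 2.2, sigma = 1.4, kappa = 0.5,
                  Gamma = matrix(1, 1, 1))
  iv <- tracks_to_intervals(
    simulate_hmm_tracks(simulation_config(1, 5000, seed = 5), p))
  fit <- fit_ml(iv, 1, n_restarts = 3, seed = 2, decode = FALSE)
  l <- iv$step[!is.na(iv$step)]
  # gamma ML in the mean/SD parameterisation: fitted mean = sample mean
  expect_equal(unname(fit$params$mu), mean(l), tolerance = 1e-3)
  expect_equal(unname(fit$params$sigma), sd(l), tolerance = 0.05)
  # wrapped Cauchy first moment: E[cos(angle)] = concentration
  a <- iv$angle[!is.na(iv$angle)]
  expect_equal(unname(fit$params$kappa), mean(cos(a)), tolerance = 0.03)
})

test_that("restarts from distinct starts agree on the optimum", {
  cfg <- simulation_config(2, 400, species = "grey", seed = 29)
  iv <- tracks_to_intervals(simulate_hmm_tracks(cfg))
  fit <- fit_ml(iv, 3, n_restarts = 4, seed = 11, decode = FALSE)
  lls <- fit$restarts$loglik
  best2 <- sort(lls[is.finite(lls)], decreasing = TRUE)[1:2]
  expect_lt(abs(diff(best2)), 0.01)
})

test_that("movement-only fits refuse known-state intervals", {
  iv <- data.frame(id = "a", step = c(1, 2), angle = c(0.1, NA),
                   known = c("free", "N"))
  expect_error(fit_ml(iv, 3, n_restarts = 1),
               "filter the data|free")
})

test_that("pseudo-residuals are standard normal under the generating model", {
  cfg <- simulation_config(4, 1000, species = "grey", seed = 37)
  iv <- tracks_to_intervals(simulate_hmm_tracks(cfg))
  res <- pseudo_residuals(iv, species_profile("grey", 3))
  for (stream in c("step_res", "angle_res")) {
    r <- res[[stream]][!is.na(res[[stream]])]
    ks <- suppressWarnings(stats::ks.test(r, "pnorm"))
    # 1% critical value of the one-sample KS statistic
    expect_lt(unname(ks$statistic), 1.628 / sqrt(length(r)))
  }
})

test_that("zero steps with a zero-mass state give finite step residuals", {
  p <- species_profile("grey", 5)
  iv <- data.frame(id = "a", step = c(1, 0, 0.5),
                   angle = c(NA, NA, 0.2),
                   known = c("free", "N", "free"))
  res <- pseudo_residuals(iv, p)
  expect_true(is.finite(res$step_res[2]))
})

test_that("BIC free-parameter count follows the stated parameterisation", {
  # 5 states, no zero mass, emission-free unknown state:
  # 4 x (mu, sigma, kappa) + 5 x 4 transitions + 4 free delta = 36
  labels <- state_labels(5)
  zm <- rep(FALSE, 4)
  p <- species_profile("grey", 5)
  w <- arsHMM:::pack_params(p, zm)
  expect_length(w, 36)
  # with zero mass on N enabled: one more
  expect_length(arsHMM:::pack_params(p, c(FALSE, FALSE, FALSE, TRUE)), 37)
})

test_that("working-scale transform round-trips parameters", {
  p <- species_profile("harbour", 5)
  zm <- c(FALSE, FALSE, FALSE, TRUE)
  w <- arsHMM:::pack_params(p, zm)
  back <- arsHMM:::unpack_params(w, p$states, zm)
  expect_equal(back$mu, p$mu, tolerance = 1e-10)
  expect_equal(back$Gamma, p$Gamma, tolerance = 1e-10)
  expect_equal(back$delta, p$delta, tolerance = 1e-10)
  expect_equal(unname(back$zeromass["N"]), unname(p$zeromass["N"]),
               tolerance = 1e-10)
})

test_that("state sequences sampled from local probabilities are calibrated", {
  # indicator rows reproduce the known state in every draw
  pr <- matrix(0, 4, 3); pr[cbind(1:4, c(2, 1, 3, 2))] <- 1
  colnames(pr) <- state_labels(3)
  dr <- sample_state_sequences(pr, n_draws = 20, seed = 1)
  expect_true(all(dr == c(2, 1, 3, 2)))
  # binomial check on a half-half row
  pr <- matrix(rep(c(0.5, 0.5, 0), 10000), ncol = 3, byrow = TRUE)
  dr <- sample_state_sequences(pr, n_draws = 1, seed = 2)
  f1 <- mean(dr == 1)
  expect_lt(abs(f1 - 0.5), 3 * sqrt(0.25 / 10000))
  # fixed seed reproduces draws
  expect_identical(sample_state_sequences(pr, 3, seed = 9),
                   sample_state_sequences(pr, 3, seed = 9))
  expect_error(sample_state_sequences(matrix(c(0.5, 0.2), 1), 1),
               "probability")
})

test_that("order selection reports coherent summaries on simulated data", {
  cfg <- simulation_config(4, 350, species = "grey",
                           movement_states_only = FALSE, seed = 53)
  iv <- tracks_to_intervals(simulate_hmm_tracks(cfg))
  rep5 <- order_selection(iv, seed = 7, n_restarts = 2)
  expect_equal(rep5$delta_bic, rep5$bic5 - rep5$bic4)
  expect_true(all(c("id", "pct_extra_ars") %in% names(rep5$per_individual)))
  expect_true(is.finite(rep5$bic4) && is.finite(rep5$bic5))
  # on data generated with two well-separated ARS scales, 5 states win
  expect_lt(rep5$bic5, rep5$bic4)
})
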