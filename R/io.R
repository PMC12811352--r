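#' Write / read a fitted HMM as JSON
#'
#' Stores every parameter, the restart table and fit summaries in plain
#' JSON so a decoded analysis can be archived or re-loaded without
#' refitting.
#'
#' @param fit an `ars_hmm_fit` from [fit_ml()].
#' @param path JSON path.
#' @return `read_hmm_fit_json()` returns a list with an [hmm_params()]
#'   object plus the stored summaries (not a full fit object).
#' @export
write_hmm_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "ars_hmm_fit"))
  p <- fit$params
  obj <- list(states = p$states, mu = p$mu, sigma = p$sigma,
              kappa = p$kappa, zeromass = p$zeromass,
              Gamma = p$Gamma, delta = p$delta,
              loglik = fit$loglik, npar = fit$npar,
              n_free_obs = fit$n_free_obs, bic = fit$bic,
              restarts = fit$restarts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hmm_fit_json
#' @export
read_hmm_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- hmm_params(obj$states, mu = unlist(obj$mu),
                       sigma = unlist(obj$sigma),
                       kappa = unlist(obj$kappa),
                       zeromass = unlist(obj$zeromass),
                       Gamma = matrix(unlist(obj$Gamma),
                                      length(obj$states), byrow = FALSE),
                       delta = unlist(obj$delta))
  list(params = params, loglik = obj$loglik, npar = obj$npar,
       n_free_obs = obj$n_free_obs, bic = obj$bic,
       restarts = as.data.frame(obj$restarts))
}

#' Write a decoded-state table as CSV
#'
#' @param intervals the interval table passed to the fit.
#' @param fit an `ars_hmm_fit` with decoding.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_decoded_csv <- function(intervals, fit, path) {
  stopifnot(inherits(fit, "ars_hmm_fit"), !is.null(fit$viterbi))
  out <- data.frame(id = intervals$id, time = intervals$time,
                    state = fit$viterbi)
  pr <- fit$state_probs
  colnames(pr) <- paste0("p_", colnames(pr))
  out <- cbind(out, as.data.frame(pr))
  if (inherits(out$time, "POSIXct"))
    out$time <- format(out$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
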