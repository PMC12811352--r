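#' Build the nested binomial use-encounter responses
#'
#' From 5-state decoded intervals, keeps the movement-state rows only
#' (non-diving and unknown intervals are excluded) and codes the two nested
#' binary responses: `ars` = 1 for focussed or broad ARS vs 0 for transit
#' (probability of ARS given encounter), and `fars` = 1 for focussed vs 0
#' for broad ARS, defined on ARS rows only (`NA` on transit rows).
#'
#' @param decoded data frame with a `state` column of 5-state labels
#'   (`fARS`, `bARS`, `Tr`, `N`, `Unk`) plus covariates and `id`.
#' @param covariates optional character vector of covariate columns; rows
#'   with missing values in any of them are dropped and counted.
#' @return a `use_encounter` data frame with `ars` and `fars` columns;
#'   dropped-row counts in `attr(, "dropped")`.
#' @export
build_response <- function(decoded, covariates = NULL) {
  st <- as.character(decoded$state)
  if (any(st == "ARS"))
    stop("4-state decoding supplied ('ARS' labels); the nested coding ",
         "requires the 5-state model")
  bad <- setdiff(unique(st), c("fARS", "bARS", "Tr", "N", "Unk"))
  if (length(bad)) stop("unknown state label(s): ", paste(bad, collapse = ", "))
  keep <- st %in% c("fARS", "bARS", "Tr")
  out <- decoded[keep, , drop = FALSE]
  dropped <- c(non_movement = sum(!keep))
  if (!is.null(covariates)) {
    cc <- rowSums(is.na(out[, covariates, drop = FALSE])) == 0
    dropped["missing_covariates"] <- sum(!cc)
    out <- out[cc, , drop = FALSE]
  }
  out$ars <- as.integer(out$state != "Tr")
  out$fars <- ifelse(out$ars == 1L, as.integer(out$state == "fARS"),
                     NA_integer_)
  if (!any(out$ars == 1L))
    warning("no ARS intervals present; the focussed-vs-broad model ",
            "cannot be fitted")
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  class(out) <- c("use_encounter", "data.frame")
  out
}

#' Specification of a use-encounter GAMM
#'
#' @param cat_terms categorical covariates entering the fixed effects.
#' @param interaction interaction order among the categorical terms (1 =
#'   main effects, 2 = all two-way, 3 = full three-way interaction).
#' @param pea include a penalised cubic-regression-spline smooth of PEA.
#' @param pea_by factor over which separate PEA smoothers are fitted
#'   (one smoother per level).
#' @param k basis dimension of each PEA smooth (>= 3).
#' @param select apply null-space shrinkage (`select = TRUE`), so an
#'   uninformative smooth can be penalised to zero.
#' @param random column holding the individual identifier, fitted as a
#'   random intercept.
#' @return a `gamm_spec` list.
#' @export
gamm_spec <- function(cat_terms = c("region", "geomorphology", "substrate"),
                      interaction = 3, pea = FALSE, pea_by = "region",
                      k = 6, select = TRUE, random = "id") {
  stopifnot(k >= 3, interaction >= 1,
            interaction <= max(1, length(cat_terms)))
  structure(list(cat_terms = cat_terms, interaction = interaction,
                 pea = pea, pea_by = pea_by, k = k, select = select,
                 random = random),
            class = "gamm_spec")
}

# expand the categorical structure into explicit model terms
expand_cat_terms <- function(cat_terms, interaction) {
  out <- character(0)
  for (ord in seq_len(interaction)) {
    if (ord > length(cat_terms)) break
    cmb <- utils::combn(cat_terms, ord, simplify = FALSE)
    out <- c(out, vapply(cmb, paste, "", collapse = ":"))
  }
  out
}

term_formula <- function(terms, spec, response, data) {
  rhs <- terms
  if ("s(pea)" %in% terms) {
    rhs <- setdiff(rhs, "s(pea)")
    by_ok <- spec$pea_by %in% names(data) &&
      nlevels(factor(data[[spec$pea_by]])) >= 2
    sm <- if (by_ok)
      sprintf("s(pea, by = %s, bs = \"cr\", k = %d)", spec$pea_by, spec$k)
    else sprintf("s(pea, bs = \"cr\", k = %d)", spec$k)
    rhs <- c(rhs, sm)
  }
  if (!is.null(spec$random) && spec$random %in% names(data) &&
      nlevels(factor(data[[spec$random]])) >= 2)
    rhs <- c(rhs, sprintf("s(%s, bs = \"re\")", spec$random))
  if (!length(rhs)) rhs <- "1"
  as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

#' Fit a use-encounter GAMM
#'
#' Penalised logistic additive model with the categorical interaction
#' structure of the specification, an optional shrinkage cubic regression
#' spline of PEA per region, and a Gaussian random intercept per individual.
#' Smoothing and variance parameters are estimated by (fast) restricted
#' marginal likelihood; large datasets use `mgcv::bam`, smaller ones
#' `mgcv::gam`. Categorical terms left with fewer than two levels in the
#' model subset are dropped with a warning, and complete separation in a
#' categorical cell is warned about (the penalty keeps estimates finite).
#'
#' @param data a [build_response()] table.
#' @param spec a [gamm_spec()].
#' @param response `"ars"` (ARS given encounter, all movement rows) or
#'   `"fars"` (focussed given ARS, ARS rows only).
#' @param engine `"auto"`, `"gam"` or `"bam"`.
#' @return the fitted mgcv model, with the spec, response and model subset
#'   attached as attributes.
#' @export
fit_gamm <- function(data, spec = gamm_spec(), response = c("ars", "fars"),
                     engine = c("auto", "gam", "bam")) {
  response <- match.arg(response)
  engine <- match.arg(engine)
  df <- as.data.frame(data)
  if (response == "fars") df <- df[!is.na(df$fars) & df$ars == 1L, ,
                                   drop = FALSE]
  if (!nrow(df)) stop("no rows available for response '", response, "'")
  cats <- spec$cat_terms
  fac <- c(cats, spec$random,
           if (spec$pea && spec$pea_by %in% names(df)) spec$pea_by)
  for (v in unique(fac)) {
    if (!v %in% names(df)) stop("covariate column '", v, "' not found")
    df[[v]] <- droplevels(factor(df[[v]]))
  }
  degenerate <- cats[vapply(cats, function(v) nlevels(df[[v]]) < 2, TRUE)]
  if (length(degenerate)) {
    warning("dropping categorical term(s) with < 2 levels: ",
            paste(degenerate, collapse = ", "))
    cats <- setdiff(cats, degenerate)
  }
  spec_used <- spec
  spec_used$cat_terms <- cats
  spec_used$interaction <- min(spec$interaction, max(1, length(cats)))
  terms <- if (length(cats))
    expand_cat_terms(cats, spec_used$interaction) else character(0)
  if (spec$pea) terms <- c(terms, "s(pea)")
  if (length(cats)) {
    cell <- interaction(df[, cats, drop = FALSE], drop = TRUE)
    mns <- tapply(df[[response]], cell, mean)
    if (any(mns == 0 | mns == 1))
      warning("complete separation in ", sum(mns %in% c(0, 1)),
              " categorical cell(s); relying on the penalty")
  }
  form <- term_formula(terms, spec_used, response, df)
  fit <- if (engine == "bam" || (engine == "auto" && nrow(df) >= 4000)) {
    mgcv::bam(form, family = stats::binomial(), data = df,
              method = "fREML", select = spec$select, discrete = TRUE)
  } else {
    mgcv::gam(form, family = stats::binomial(), data = df,
              method = "REML", select = spec$select)
  }
  attr(fit, "ars_spec") <- spec_used
  attr(fit, "ars_response") <- response
  attr(fit, "ars_terms") <- terms
  attr(fit, "ars_data") <- df
  fit
}

# terms droppable under marginality: not nested inside any other term
droppable_terms <- function(terms, spec) {
  vars_of <- function(tm) {
    if (tm == "s(pea)") return(c("pea", spec$pea_by))
    strsplit(tm, ":", fixed = TRUE)[[1]]
  }
  vapply(terms, function(a) {
    va <- vars_of(a)
    !any(vapply(setdiff(terms, a), function(b) all(va %in% vars_of(b)),
                TRUE))
  }, TRUE)
}

refit_terms <- function(df, terms, spec, response) {
  form <- term_formula(terms, spec, response, df)
  if (nrow(df) >= 4000) {
    mgcv::bam(form, family = stats::binomial(), data = df,
              method = "fREML", select = spec$select, discrete = TRUE)
  } else {
    mgcv::gam(form, family = stats::binomial(), data = df,
              method = "REML", select = spec$select)
  }
}

#' Backwards model selection by AIC
#'
#' Starting from the full specification, iteratively removes the candidate
#' term whose removal gives the lowest AIC, whenever that removal lowers the
#' AIC or raises it by at most `threshold` (boundary included). Marginality
#' is honoured: a term is only a removal candidate while no retained
#' higher-order term contains it (the PEA smooth, fitted by region, counts
#' as containing the region main effect). The PEA basis dimension is first
#' chosen over `k_grid` by minimum AIC. AIC uses the effective degrees of
#' freedom of the penalised fit.
#'
#' @param data a [build_response()] table.
#' @param spec the full [gamm_spec()].
#' @param response `"ars"` or `"fars"`.
#' @param k_grid candidate PEA basis dimensions.
#' @param threshold the AIC increase up to which a term is still removed.
#' @return list with the final `fit`, retained `terms`, chosen `k`, and a
#'   `trace` data frame recording every candidate AIC.
#' @export
select_model <- function(data, spec = gamm_spec(),
                         response = c("ars", "fars"),
                         k_grid = c(4, 5, 6, 8, 10), threshold = 2) {
  response <- match.arg(response)
  full <- fit_gamm(data, spec, response)
  spec_used <- attr(full, "ars_spec")
  df <- attr(full, "ars_data")
  terms <- attr(full, "ars_terms")
  trace <- list()
  k_best <- spec_used$k
  if (spec_used$pea) {
    aics <- vapply(k_grid, function(kk) {
      sk <- spec_used; sk$k <- kk
      AIC(refit_terms(df, terms, sk, response))
    }, 0)
    k_best <- k_grid[which.min(aics)]
    spec_used$k <- k_best
    trace[[1]] <- data.frame(step = 0L, action = "choose_k",
                             candidate = as.character(k_grid), aic = aics,
                             stringsAsFactors = FALSE)
    full <- refit_terms(df, terms, spec_used, response)
  }
  cur_fit <- full
  cur_aic <- AIC(cur_fit)
  step <- 0L
  repeat {
    step <- step + 1L
    cand <- terms[droppable_terms(terms, spec_used)]
    if (!length(cand)) break
    aics <- vapply(cand, function(tm)
      AIC(refit_terms(df, setdiff(terms, tm), spec_used, response)), 0)
    trace[[length(trace) + 1]] <- data.frame(
      step = step, action = "drop", candidate = cand, aic = aics,
      stringsAsFactors = FALSE)
    j <- which.min(aics)
    if (aics[j] <= cur_aic + threshold) {
      terms <- setdiff(terms, cand[j])
      cur_fit <- refit_terms(df, terms, spec_used, response)
      cur_aic <- AIC(cur_fit)
    } else break
  }
  attr(cur_fit, "ars_spec") <- spec_used
  attr(cur_fit, "ars_response") <- response
  attr(cur_fit, "ars_terms") <- terms
  attr(cur_fit, "ars_data") <- df
  list(fit = cur_fit, terms = terms, k = k_best,
       trace = do.call(rbind, trace))
}

# eigenvalue-clipped nearest positive-definite repair
near_pd <- function(V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (all(e$values > 0)) return(V)
  warning("coefficient covariance not positive definite; ",
          "clipping eigenvalues")
  lam <- pmax(e$values, 1e-10 * max(abs(e$values)))
  e$vectors %*% (lam * t(e$vectors))
}

random_effect_labels <- function(fit) {
  labs <- vapply(fit$smooth, function(s)
    if (inherits(s, "random.effect")) s$label else NA_character_, "")
  labs[!is.na(labs)]
}

draw_probs <- function(fit, newdata, n_draws, point = FALSE) {
  nd <- as.data.frame(newdata)
  dat <- attr(fit, "ars_data")
  for (v in names(dat)) {
    if (is.factor(dat[[v]])) {
      if (!v %in% names(nd)) nd[[v]] <- levels(dat[[v]])[1]
      nd[[v]] <- factor(nd[[v]], levels = levels(dat[[v]]))
    } else if (!v %in% names(nd) && is.numeric(dat[[v]])) {
      nd[[v]] <- median(dat[[v]], na.rm = TRUE)
    }
  }
  re <- random_effect_labels(fit)
  Xp <- predict(fit, newdata = nd, type = "lpmatrix",
                exclude = if (length(re)) re else NULL,
                discrete = FALSE, newdata.guaranteed = TRUE)
  if (point) return(as.numeric(plogis(Xp %*% coef(fit))))
  V <- near_pd(vcov(fit))
  B <- mgcv::rmvn(n_draws, coef(fit), V)
  if (is.null(dim(B))) B <- matrix(B, nrow = n_draws)
  plogis(B %*% t(Xp))
}

#' Posterior-draw prediction with probability propagation
#'
#' Coefficient vectors are drawn from a multivariate normal with the fitted
#' mean and covariance of each model; random intercepts are set to zero
#' (population-level curves). Per draw, the inverse-logit predictions of
#' model (i), P(ARS | encounter), are multiplied by those of model (ii),
#' P(focussed | ARS), giving the overall probability of focussed ARS, and by
#' their complement for broad ARS — so P(fARS) + P(bARS) = P(ARS | enc)
#' holds exactly per draw.
#'
#' @param fit_ars,fit_fars fitted models from [fit_gamm()] for the two
#'   nested responses.
#' @param newdata prediction grid (habitat/region combinations, or a PEA
#'   sequence).
#' @param n_draws number of posterior draws.
#' @param seed optional integer seed.
#' @return an object of class `prediction_draws` holding the grid and the
#'   draw matrices `p_ars`, `p_fars_given_ars`, `p_fars`, `p_bars`
#'   (draws x rows); see [summary.prediction_draws()].
#' @export
posterior_predict <- function(fit_ars, fit_fars, newdata, n_draws = 1000,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p1 <- draw_probs(fit_ars, newdata, n_draws)
  p2 <- draw_probs(fit_fars, newdata, n_draws)
  p_fars <- p1 * p2
  structure(list(grid = as.data.frame(newdata), n_draws = n_draws,
                 p_ars = p1, p_fars_given_ars = p2,
                 p_fars = p_fars, p_bars = p1 - p_fars),
            class = "prediction_draws")
}

#' Summarise posterior prediction draws
#'
#' @param object a [posterior_predict()] result.
#' @param probs interval probabilities.
#' @param ... unused.
#' @return the prediction grid with mean and interval columns for
#'   P(ARS | enc), P(fARS | ARS), P(fARS) and P(bARS).
#' @export
summary.prediction_draws <- function(object, probs = c(0.025, 0.975), ...) {
  out <- object$grid
  for (q in c("p_ars", "p_fars_given_ars", "p_fars", "p_bars")) {
    m <- object[[q]]
    out[[paste0(q, "_mean")]] <- colMeans(m)
    out[[paste0(q, "_lo")]] <- apply(m, 2, quantile, probs[1])
    out[[paste0(q, "_hi")]] <- apply(m, 2, quantile, probs[2])
  }
  out
}

#' Regional prevalence of each ARS scale
#'
#' Fits both nested models with region as the sole fixed effect (plus the
#' individual random intercept) and predicts per region with full
#' probability propagation.
#'
#' @param data a [build_response()] table with a `region` column.
#' @param n_draws posterior draws.
#' @param seed optional integer seed.
#' @param random individual-identifier column.
#' @return a `prediction_draws` object with one grid row per region, with
#'   the two fitted models attached as attributes.
#' @export
region_prevalence <- function(data, n_draws = 1000, seed = NULL,
                              random = "id") {
  spec <- gamm_spec(cat_terms = "region", interaction = 1, pea = FALSE,
                    random = random)
  fit1 <- fit_gamm(data, spec, "ars")
  fit2 <- fit_gamm(data, spec, "fars")
  regions <- sort(unique(as.character(data$region)))
  out <- posterior_predict(fit1, fit2, data.frame(region = regions),
                           n_draws = n_draws, seed = seed)
  attr(out, "fit_ars") <- fit1
  attr(out, "fit_fars") <- fit2
  out
}

#' Sensitivity of predictions to state-assignment uncertainty
#'
#' Per iteration, a new state sequence is drawn from the HMM's local state
#' probabilities, the nested responses are rebuilt, the region-prevalence
#' models are refitted and their point predictions stored; the spread of
#' predictions across iterations measures how much state uncertainty
#' propagates into the habitat results.
#'
#' @param probs T x K local state probability matrix with state labels as
#'   column names, row-aligned with `habitat`.
#' @param habitat data frame of per-interval covariates (`region`, `id`,
#'   ...), one row per interval.
#' @param n_iter number of resampling iterations.
#' @param seed optional integer seed.
#' @param random individual-identifier column.
#' @return list with the per-iteration prediction matrix (`iterations` x
#'   prediction rows), the prediction `grid`, a `summary` data frame
#'   (mean, SD, range over iterations) and the count of failed iterations.
#' @export
state_uncertainty_sensitivity <- function(probs, habitat, n_iter = 100,
                                          seed = NULL, random = "id") {
  if (!is.null(seed)) set.seed(seed)
  states <- colnames(probs)
  if (is.null(states)) stop("probs must have state labels as column names")
  draws <- sample_state_sequences(probs, n_draws = n_iter)
  regions <- sort(unique(as.character(habitat$region)))
  grid <- data.frame(region = regions)
  res <- matrix(NA_real_, n_iter, 2 * length(regions))
  colnames(res) <- c(paste0("p_ars.", regions),
                     paste0("p_fars_given_ars.", regions))
  n_failed <- 0
  for (it in seq_len(n_iter)) {
    df <- habitat
    df$state <- states[draws[, it]]
    ok <- tryCatch({
      resp <- suppressWarnings(build_response(df))
      spec <- gamm_spec(cat_terms = "region", interaction = 1, pea = FALSE,
                        random = random)
      f1 <- suppressWarnings(fit_gamm(resp, spec, "ars"))
      f2 <- suppressWarnings(fit_gamm(resp, spec, "fars"))
      res[it, ] <- c(draw_probs(f1, grid, 0, point = TRUE),
                     draw_probs(f2, grid, 0, point = TRUE))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) n_failed <- n_failed + 1
  }
  ok_rows <- rowSums(is.na(res)) == 0
  summ <- data.frame(quantity = colnames(res),
                     mean = colMeans(res[ok_rows, , drop = FALSE]),
                     sd = apply(res[ok_rows, , drop = FALSE], 2, sd),
                     min = apply(res[ok_rows, , drop = FALSE], 2, min),
                     max = apply(res[ok_rows, , drop = FALSE], 2, max),
                     row.names = NULL)
  list(predictions = res, grid = grid, summary = summ, n_failed = n_failed)
}

#' Within-individual residual autocorrelation
#'
#' Deviance-residual autocorrelation at lags 1-10 within each individual,
#' with approximate 95% white-noise bands (1.96 / sqrt(n)).
#'
#' @param fit a model from [fit_gamm()].
#' @param lags lags to report.
#' @return data frame `id`, `lag`, `r`, `band`; individuals with fewer than
#'   two residuals are skipped and listed in `attr(, "skipped")`.
#' @export
residual_autocorrelation <- function(fit, lags = 1:10) {
  df <- attr(fit, "ars_data")
  if (is.null(df)) stop("fit was not produced by fit_gamm()")
  r <- residuals(fit, type = "deviance")
  out <- list(); skipped <- character(0)
  for (ind in unique(as.character(df[[attr(fit, "ars_spec")$random]]))) {
    ri <- r[as.character(df[[attr(fit, "ars_spec")$random]]) == ind]
    n <- length(ri)
    if (n < 2) { skipped <- c(skipped, ind); next }
    lmax <- min(max(lags), n - 1)
    ac <- acf(ri, lag.max = lmax, plot = FALSE)$acf[-1]
    use <- lags[lags <= lmax]
    out[[length(out) + 1]] <- data.frame(id = ind, lag = use, r = ac[use],
                                         band = 1.96 / sqrt(n),
                                         stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "skipped") <- skipped
  res
}
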