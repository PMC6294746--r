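#' Model specification for individual-spindle mixed models
#'
#' Separates predictors into *key predictors* — whose full interaction
#' seeds the model and whose main effects are tested — and *candidate
#' covariates*, which the stepwise-AIC search may add to soak up residual
#' variance. Every participant contributes a random intercept.
#'
#' @param dependent dependent column name (log-transform beforehand if
#'   desired, e.g. `log_power`).
#' @param key_predictors character vector of key predictor columns.
#' @param candidate_covariates character vector of candidate covariates.
#' @param grouping participant (random-intercept) column.
#' @return list of class `spd_model_spec`.
#' @export
model_spec <- function(dependent, key_predictors,
                       candidate_covariates = character(),
                       grouping = "participant") {
  stopifnot(!dependent %in% c(key_predictors, candidate_covariates))
  structure(list(dependent = dependent, key_predictors = key_predictors,
                 candidate_covariates = candidate_covariates,
                 grouping = grouping),
            class = "spd_model_spec")
}

.key_design <- function(tbl, key_predictors) {
  f <- stats::reformulate(paste(key_predictors, collapse = " * "))
  stats::model.matrix(f, tbl)
}

#' Residualize candidate covariates against the key predictors
#'
#' Replaces each covariate by the residuals of an ordinary least-squares
#' regression on the full key-predictor interaction design (with
#' intercept). The new covariates are orthogonal to the key design, so
#' adding them later cannot inflate the variance of the key-effect
#' estimates through collinearity.
#'
#' @param tbl data.frame of individual spindles.
#' @param covariates columns to residualize.
#' @param key_predictors key predictor columns.
#' @return `tbl` with the covariate columns replaced by residuals.
#' @export
residualize_covariates <- function(tbl, covariates, key_predictors) {
  need <- c(covariates, key_predictors)
  miss <- setdiff(need, names(tbl))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(tbl[, need])) stop("missing values in model columns")
  X <- .key_design(tbl, key_predictors)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])]
    stop("rank-deficient key-predictor design; aliased: ",
         paste(aliased, collapse = ", "))
  }
  for (cv in covariates)
    tbl[[cv]] <- qr.resid(qx, as.numeric(tbl[[cv]]))
  tbl
}

.canon_term <- function(term) {
  paste(sort(strsplit(term, ":", fixed = TRUE)[[1L]]), collapse = ":")
}

.term_vars <- function(term) strsplit(term, ":", fixed = TRUE)[[1L]]

#' Stepwise-AIC covariate selection around a fixed key-predictor seed
#'
#' Starts from the full interaction of the key predictors and searches, by
#' ordinary (fixed-effects-only) linear regression, the move that most
#' improves AIC: add a candidate covariate, add a two-way interaction
#' between an in-model candidate and another in-model term, or drop a
#' non-seed term. Marginality is respected (a main effect is not dropped
#' while one of its interactions remains) and seed terms are never
#' dropped. Ties are broken by lexicographic term order, making the search
#' deterministic.
#'
#' @param tbl residualized data.frame.
#' @param spec a [model_spec()].
#' @param max_steps step budget; exceeding it is an error.
#' @return character vector of selected fixed-effect terms.
#' @export
stepwise_select <- function(tbl, spec, max_steps = 200) {
  stopifnot(inherits(spec, "spd_model_spec"))
  seed <- attr(stats::terms(
    stats::reformulate(paste(spec$key_predictors, collapse = " * "))),
    "term.labels")
  seed <- vapply(seed, .canon_term, "")
  current <- seed
  aic_of <- function(terms) {
    f <- if (length(terms)) stats::reformulate(terms, spec$dependent)
         else stats::reformulate("1", spec$dependent)
    stats::AIC(stats::lm(f, data = tbl))
  }
  best_aic <- aic_of(current)
  for (step in seq_len(max_steps + 1L)) {
    if (step > max_steps) stop("stepwise selection exceeded ", max_steps, " steps")
    moves <- list()
    mains <- current[!grepl(":", current, fixed = TRUE)]
    for (cv in setdiff(spec$candidate_covariates, current))
      moves[[paste0("+", cv)]] <- c(current, cv)
    in_model_cands <- intersect(spec$candidate_covariates, current)
    for (cv in in_model_cands) for (tm in setdiff(mains, cv)) {
      it <- .canon_term(paste(cv, tm, sep = ":"))
      if (!it %in% current) moves[[paste0("+", it)]] <- c(current, it)
    }
    for (tm in setdiff(current, seed)) {
      vars <- .term_vars(tm)
      blocked <- length(vars) == 1L &&
        any(vapply(current[current != tm],
                   function(o) vars %in% .term_vars(o), TRUE))
      if (!blocked) moves[[paste0("-", tm)]] <- setdiff(current, tm)
    }
    if (!length(moves)) break
    moves <- moves[order(names(moves))]
    aics <- vapply(moves, aic_of, 0)
    j <- which.min(aics)             # first minimum = lexicographic tie-break
    if (aics[j] < best_aic - 1e-8) {
      current <- moves[[j]]
      best_aic <- aics[j]
    } else break
  }
  current
}

#' Fit a linear mixed model on individual spindles
#'
#' Fixed effects as given, plus a random intercept per grouping level,
#' fitted by maximum likelihood (not REML) so that fits are comparable via
#' likelihood-ratio tests.
#'
#' @param tbl data.frame.
#' @param dependent dependent column.
#' @param terms character vector of fixed-effect terms (may be empty for
#'   an intercept-only model).
#' @param grouping grouping (random-intercept) column.
#' @return object of class `spd_lmm_fit`: list with `coefficients`
#'   (estimate, SE, T), `logLik`, `AIC`, `sigma_u`, `sigma_e`, `n_obs`,
#'   `terms`, and the underlying `lme4` fit as `fit`.
#' @export
fit_lmm <- function(tbl, dependent, terms, grouping = "participant") {
  stopifnot(grouping %in% names(tbl), dependent %in% names(tbl))
  if (length(unique(tbl[[grouping]])) < 2L)
    stop("need at least 2 grouping levels")
  rhs <- c(if (length(terms)) terms else "1",
           paste0("(1 | ", grouping, ")"))
  f <- stats::as.formula(paste(dependent, "~", paste(rhs, collapse = " + ")))
  fx <- if (length(terms)) stats::reformulate(terms, dependent)
        else stats::reformulate("1", dependent)
  X <- stats::model.matrix(stats::delete.response(stats::terms(fx)), tbl)
  if (qr(X)$rank < ncol(X))
    stop("fixed-effect design is rank deficient (inestimable terms)")
  fit <- lme4::lmer(f, data = tbl, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  if (lme4::isSingular(fit))
    warning("singular fit: random-intercept variance estimated at zero")
  co <- stats::coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  ll <- stats::logLik(fit)
  structure(list(coefficients = data.frame(term = rownames(co),
                                           estimate = co[, "Estimate"],
                                           se = co[, "Std. Error"],
                                           t = co[, "t value"],
                                           row.names = NULL),
                 logLik = as.numeric(ll), df = attr(ll, "df"),
                 AIC = stats::AIC(fit),
                 sigma_u = vc$sdcor[vc$grp == grouping & vc$var1 == "(Intercept)"],
                 sigma_e = vc$sdcor[vc$grp == "Residual"],
                 n_obs = stats::nobs(fit),
                 terms = terms, dependent = dependent, grouping = grouping,
                 fit = fit),
            class = "spd_lmm_fit")
}

#' @exportS3Method base::print
print.spd_lmm_fit <- function(x, ...) {
  cat(sprintf("<spd_lmm_fit> %s ~ %s + (1 | %s)\n", x$dependent,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
              x$grouping))
  cat(sprintf("  n = %d, logLik = %.2f, AIC = %.2f, sigma_u = %.3f, sigma_e = %.3f\n",
              x$n_obs, x$logLik, x$AIC, x$sigma_u, x$sigma_e))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test between nested mixed-model fits
#'
#' @param full,reduced `spd_lmm_fit` objects fitted by ML on the same rows;
#'   the reduced model's terms must nest in the full model's.
#' @return list of class `spd_lr_test`: `chi2`, `df`, `p`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "spd_lmm_fit"), inherits(reduced, "spd_lmm_fit"))
  if (!all(reduced$terms %in% full$terms))
    stop("models are not nested (reduced terms not a subset)")
  if (full$n_obs != reduced$n_obs)
    stop("models were fitted on different numbers of rows")
  chi2 <- 2 * (full$logLik - reduced$logLik)
  if (chi2 < -1e-6) stop("negative likelihood-ratio statistic: ",
                         "fits are inconsistent or not nested")
  chi2 <- max(0, chi2)
  df <- full$df - reduced$df
  if (df < 1L) stop("degrees-of-freedom difference must be >= 1")
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "spd_lr_test")
}

#' @exportS3Method base::print
print.spd_lr_test <- function(x, ...) {
  cat(sprintf("LR chi2(%d) = %.3f, p = %.4g\n", x$df, x$chi2, x$p))
  invisible(x)
}

#' Terms that survive removing a factor and everything containing it
#'
#' The main effect of a key predictor is tested by dropping the predictor
#' together with every interaction term that contains it, then comparing
#' the reduced fit to the full fit with a likelihood-ratio test.
#'
#' @param terms character vector of model terms.
#' @param variable variable whose terms are removed.
#' @return the reduced term vector.
#' @export
terms_without <- function(terms, variable) {
  keep <- !vapply(terms, function(tm) variable %in% .term_vars(tm), TRUE)
  terms[keep]
}

#' Full individual-spindle mixed-model analysis
#'
#' Residualizes the candidate covariates against the key predictors, runs
#' the stepwise-AIC covariate search, fits the selected model as a linear
#' mixed model by ML, and tests each key predictor's main effect (the
#' predictor plus all terms containing it) by likelihood ratio.
#'
#' @param tbl data.frame of individual spindles.
#' @param spec a [model_spec()].
#' @param max_steps stepwise budget.
#' @return list with `fit` (full `spd_lmm_fit`), `selected` terms and
#'   `tests` (named list of `spd_lr_test`, one per key predictor).
#' @export
lmm_analysis <- function(tbl, spec, max_steps = 200) {
  stopifnot(inherits(spec, "spd_model_spec"))
  if (length(spec$candidate_covariates))
    tbl <- residualize_covariates(tbl, spec$candidate_covariates,
                                  spec$key_predictors)
  selected <- stepwise_select(tbl, spec, max_steps = max_steps)
  full <- fit_lmm(tbl, spec$dependent, selected, spec$grouping)
  tests <- lapply(spec$key_predictors, function(kp) {
    reduced <- fit_lmm(tbl, spec$dependent, terms_without(selected, kp),
                       spec$grouping)
    lr_test(full, reduced)
  })
  names(tests) <- spec$key_predictors
  list(fit = full, selected = selected, tests = tests)
}
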