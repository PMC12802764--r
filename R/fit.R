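#' Fit a logistic regression by maximum likelihood
#'
#' Thin, validated wrapper around iteratively reweighted least squares
#' (`stats::glm`, binomial family, logit link). Refuses non-binary
#' responses, single-class responses, rank-deficient designs and fits
#' showing signs of complete separation (diverging coefficients).
#'
#' @param data data.frame containing the response and predictors.
#' @param formula model formula with a 0/1 response on the left.
#' @return object of class `fit_result`: `coefficients`, `se`, `z`,
#'   `p_value` (two-sided Wald), `log_likelihood`, `n`, `k`, `converged`,
#'   `fitted`, plus the underlying `glm` object in `$glm`.
#' @export
fit_logistic <- function(data, formula) {
  y <- stats::model.response(stats::model.frame(formula, data))
  if (!all(y %in% c(0, 1))) stop("response must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  fit <- stats::glm(formula, family = stats::binomial(), data = data,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 50))
  if (fit$rank < length(stats::coef(fit))) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  co <- stats::coef(fit)
  sm <- summary(fit)
  if (!fit$converged || any(abs(co) > 25) ||
      any(sm$coefficients[, "Std. Error"] > 100)) {
    stop("logistic fit diverged (possible complete separation)", call. = FALSE)
  }
  structure(list(coefficients = co,
                 se = sm$coefficients[, "Std. Error"],
                 z = sm$coefficients[, "z value"],
                 p_value = sm$coefficients[, "Pr(>|z|)"],
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 n = length(y), k = length(co),
                 converged = fit$converged,
                 fitted = stats::fitted(fit), y = y,
                 formula = formula, glm = fit),
            class = "fit_result")
}

#' Fit one of the two outcome models on a cohort table
#'
#' Builds the standard design (age in decades, natural-log lesion volume,
#' and either brain volume in dm^3 or logit BPF) and fits
#' `mrs_gt2 ~ age_decades + sex_male + htn + dm2 + nonsmoker + log_dwiv + X`.
#'
#' @param cohort cohort table including `mrs_gt2`.
#' @param flavor `"bv"` or `"bpf"`.
#' @return a `fit_result` (see [fit_logistic()]).
#' @export
fit_outcome_model <- function(cohort, flavor = c("bv", "bpf")) {
  flavor <- match.arg(flavor)
  mf <- model_frame(cohort, flavor)
  imaging <- if (flavor == "bv") "brain_volume_dm3" else "logit_bpf"
  f <- stats::as.formula(paste(
    "mrs_gt2 ~ age_decades + sex_male + htn + dm2 + nonsmoker + log_dwiv +",
    imaging))
  fit_logistic(mf, f)
}

#' Bayes information criterion of a fit
#'
#' `k * log(n) - 2 * log-likelihood`; lower is better.
#'
#' @param fit a `fit_result`.
#' @return scalar BIC.
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  if (!isTRUE(fit$converged)) {
    stop("BIC refused: fit did not converge", call. = FALSE)
  }
  fit$k * log(fit$n) - 2 * fit$log_likelihood
}

raftery_strength <- function(delta_abs) {
  if (delta_abs <= 2) "weak"
  else if (delta_abs <= 6) "positive"
  else if (delta_abs <= 10) "strong"
  else "very strong"
}

#' Compare two fitted models by BIC
#'
#' Computes `delta_bic = bic(fit_a) - bic(fit_b)` and grades the evidence
#' for the preferred (lower-BIC) model on the conventional Raftery scale:
#' |dBIC| in (0, 2] weak, (2, 6] positive, (6, 10] strong, above 10 very
#' strong.
#'
#' @param fit_a,fit_b `fit_result`s on the same subjects and outcomes.
#' @param labels length-2 character naming the two models.
#' @return object of class `model_comparison`: `bic_a`, `bic_b`,
#'   `delta_bic`, `preferred`, `strength`.
#' @export
compare_models <- function(fit_a, fit_b, labels = c("bpf", "bv")) {
  stopifnot(inherits(fit_a, "fit_result"), inherits(fit_b, "fit_result"))
  if (fit_a$n != fit_b$n) stop("models were fitted on different n", call. = FALSE)
  if (!isTRUE(all.equal(fit_a$y, fit_b$y))) {
    stop("models were fitted on different outcome vectors", call. = FALSE)
  }
  ba <- bic(fit_a); bb <- bic(fit_b)
  delta <- ba - bb
  preferred <- if (delta > 0) labels[2] else if (delta < 0) labels[1] else "none"
  structure(list(bic_a = ba, bic_b = bb, delta_bic = delta,
                 preferred = preferred, labels = labels,
                 strength = raftery_strength(abs(delta))),
            class = "model_comparison")
}

#' Variance inflation factors
#'
#' For each predictor, `1 / (1 - R^2)` from the ordinary least-squares
#' regression of that predictor on all others (with intercept). Values are
#' flagged infinite under perfect collinearity.
#'
#' @param data data.frame of predictor values.
#' @param predictors column names to assess (default: all columns).
#' @return data.frame with `predictor`, `vif`, `infinite`.
#' @export
vif <- function(data, predictors = names(data)) {
  stopifnot(length(predictors) >= 2)
  X <- data[predictors]
  if (any(vapply(X, function(c) stats::var(as.numeric(c)) == 0, logical(1)))) {
    stop("predictors must be non-constant", call. = FALSE)
  }
  out <- lapply(predictors, function(p) {
    f <- stats::as.formula(paste0("`", p, "` ~ ."))
    r2 <- summary(stats::lm(f, data = X))$r.squared
    inf <- r2 > 1 - 1e-10
    data.frame(predictor = p, vif = if (inf) Inf else 1 / (1 - r2),
               infinite = inf)
  })
  do.call(rbind, out)
}

#' Box-Tidwell check of linearity in the logit
#'
#' For each continuous term `x`, refits the model with an added
#' `u * log(u)` term, where `u` is `x` shifted to be strictly positive
#' (`u = x - min(x) + 1` when `x` has non-positive values). A small Wald
#' p-value for the added term signals departure from linearity in the
#' logit; the check passes at `p >= alpha`.
#'
#' @param data model frame used for the original fit.
#' @param fit the original `fit_result`.
#' @param continuous_terms names of continuous predictors to check.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with `term`, `p_value`, `pass`, `inconclusive`.
#' @export
linearity_in_logit <- function(data, fit, continuous_terms, alpha = 0.05) {
  stopifnot(inherits(fit, "fit_result"))
  rows <- lapply(continuous_terms, function(term) {
    x <- data[[term]]
    if (is.null(x)) stop("unknown term: ", term, call. = FALSE)
    if (stats::var(x) == 0) {
      stop("continuous term is constant: ", term, call. = FALSE)
    }
    u <- if (min(x) <= 0) x - min(x) + 1 else x
    aug <- data
    aug[[".bt"]] <- u * log(u)
    f <- stats::update(fit$formula, . ~ . + .bt)
    res <- tryCatch({
      afit <- fit_logistic(aug, f)
      p <- unname(afit$p_value[".bt"])
      data.frame(term = term, p_value = p, pass = p >= alpha,
                 inconclusive = FALSE)
    }, error = function(e) {
      data.frame(term = term, p_value = NA_real_, pass = NA,
                 inconclusive = TRUE)
    })
    res
  })
  do.call(rbind, rows)
}

#' Influence diagnostics for a logistic fit
#'
#' Cook's distances (from leverage and standardized Pearson residuals) per
#' record; records with distance above `threshold` are flagged as strongly
#' influential.
#'
#' @param fit a `fit_result`.
#' @param threshold flagging threshold on Cook's distance (default 1).
#' @return data.frame with `cooks_distance`, `leverage`,
#'   `std_pearson_residual`, `flagged`.
#' @export
influence_diagnostics <- function(fit, threshold = 1) {
  stopifnot(inherits(fit, "fit_result"))
  d <- stats::cooks.distance(fit$glm)
  h <- stats::hatvalues(fit$glm)
  r <- stats::rstandard(fit$glm, type = "pearson")
  data.frame(cooks_distance = as.numeric(d), leverage = as.numeric(h),
             std_pearson_residual = as.numeric(r), flagged = d > threshold)
}

#' No-intercept agreement regression
#'
#' Least-squares slope through the origin, `sum(x*y) / sum(x^2)`, with its
#' standard error — the convention for comparing two measurements of the
#' same quantity (e.g. automated vs manual ICV), where a slope of 1 means
#' perfect agreement.
#'
#' @param x,y paired measurements (at least 2, `sum(x^2) > 0`).
#' @return list with `slope`, `se`, `n`.
#' @export
no_intercept_agreement <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (sum(x^2) == 0) stop("x must not be identically zero", call. = FALSE)
  fit <- stats::lm(y ~ 0 + x)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm[1, 1]), se = unname(sm[1, 2]), n = length(x))
}
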