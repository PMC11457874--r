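# Stressor-response models: logistic regression of the binary indicator
# "FSBI worse than reference" on percent surface fines, fitted per site
# class x stream order, then inverted to SF benchmarks (SR50, SR75).

#' Binary worse-than-reference response
#'
#' Label 1 if FSBI is strictly less than the class FSBI reference
#' benchmark, 0 otherwise (an event exactly at the benchmark achieves it).
#'
#' @param fsbi FSBI values.
#' @param fsbi_ref The FSBI_ref benchmark (single value, recycled).
#' @return Integer vector of 0/1 labels.
#' @export
make_response <- function(fsbi, fsbi_ref) {
  if (any(!is.finite(fsbi_ref))) stop_sedbench("missing FSBI_ref benchmark")
  as.integer(fsbi < fsbi_ref)
}

#' Construct a logistic stressor-response model from known coefficients
#'
#' Builds an `sr_logistic` object from published or externally fitted
#' coefficients so they can be inverted to benchmarks without refitting.
#'
#' @param beta0 Intercept on the log-odds scale.
#' @param beta1 Slope, log-odds per percent SF.
#' @param se0,se1 Standard errors (optional).
#' @param site_class,order Optional cell identifiers.
#' @param n Number of events behind the fit (optional).
#' @return An object of class `sr_logistic` with `converged = TRUE`.
#' @export
logistic_model <- function(beta0, beta1, se0 = NA_real_, se1 = NA_real_,
                           site_class = NA_character_, order = NA_integer_,
                           n = NA_integer_) {
  stopifnot(is.finite(beta0), is.finite(beta1))
  structure(list(site_class = site_class, order = as.integer(order),
                 beta0 = as.numeric(beta0), beta1 = as.numeric(beta1),
                 se0 = se0, se1 = se1,
                 null_deviance = NA_real_, residual_deviance = NA_real_,
                 n = as.integer(n), converged = TRUE, method = "supplied"),
            class = "sr_logistic")
}

#' @export
print.sr_logistic <- function(x, ...) {
  cat("Logistic stressor-response model")
  if (!is.na(x$site_class) || !is.na(x$order))
    cat(sprintf(" [%s, order %s]", x$site_class, x$order))
  cat("\n")
  cat(sprintf("  logit P(FSBI worse) = %.4f + %.4f * SF   (n = %s)\n",
              x$beta0, x$beta1, ifelse(is.na(x$n), "?", x$n)))
  if (is.finite(x$se1))
    cat(sprintf("  SE: intercept %.4f, slope %.4f\n", x$se0, x$se1))
  if (is.finite(x$residual_deviance))
    cat(sprintf("  deviance: null %.2f, residual %.2f\n",
                x$null_deviance, x$residual_deviance))
  invisible(x)
}

logistic_loglik <- function(beta0, beta1, sf, y) {
  eta <- beta0 + beta1 * sf
  sum(y * eta - log1p(exp(eta)))
}

#' Fit the logistic stressor-response model
#'
#' Maximum-likelihood fit of `logit P(worse) = beta0 + beta1 * SF` by
#' iteratively reweighted least squares (Newton-Raphson). Standard errors
#' come from the observed information at the optimum. Complete or
#' quasi-complete separation is detected and raised as an error rather than
#' returning diverging coefficients.
#'
#' @param sf Percent surface fines (predictor).
#' @param labels 0/1 response, see [make_response()].
#' @param site_class,order Optional cell identifiers recorded on the model.
#' @param min_n Minimum number of events (default 10).
#' @param max_iter,tol IRLS iteration controls.
#' @return An object of class `sr_logistic`.
#' @export
fit_logistic <- function(sf, labels, site_class = NA_character_,
                         order = NA_integer_, min_n = 10,
                         max_iter = 100, tol = 1e-12) {
  keep <- is.finite(sf) & is.finite(labels)
  sf <- sf[keep]; y <- as.numeric(labels[keep])
  n <- length(sf)
  if (n < min_n)
    stop_sedbench("need at least ", min_n, " events to fit, got ", n)
  if (!all(y %in% c(0, 1))) stop_sedbench("labels must be 0/1")
  if (length(unique(y)) < 2)
    stop_sedbench("single-label data: both response values must be present")

  X <- cbind(1, sf)
  p0 <- mean(y)
  beta <- c(stats::qlogis(p0), 0)
  ll_old <- logistic_loglik(beta[1], beta[2], sf, y)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    if (all(w < 1e-12)) break
    z <- eta + (y - p) / pmax(w, 1e-12)
    beta_new <- stats::coef(stats::lm.wfit(X, z, w))
    ll_new <- logistic_loglik(beta_new[1], beta_new[2], sf, y)
    # step-halving keeps Newton monotone on awkward instances
    step <- 1
    while (ll_new < ll_old - 1e-12 && step > 1e-4) {
      step <- step / 2
      beta_new <- beta + step * (beta_new - beta)
      ll_new <- logistic_loglik(beta_new[1], beta_new[2], sf, y)
    }
    done <- max(abs(beta_new - beta)) < tol || abs(ll_new - ll_old) < tol
    beta <- beta_new; ll_old <- ll_new
    if (done) { converged <- TRUE; break }
  }
  eta <- as.numeric(X %*% beta)
  p <- stats::plogis(eta)
  # separation: fitted probabilities indistinguishable from the labels with
  # runaway linear predictors
  if (max(abs(eta)) > 25 && all(abs(y - p) < 1e-6))
    stop_sedbench("complete separation detected: SF perfectly classifies ",
                  "the response; logistic MLE does not exist")
  if (!converged)
    warn_sedbench("IRLS did not fully converge in ", max_iter, " iterations")
  w <- pmax(p * (1 - p), 1e-12)
  info <- crossprod(X, X * w)
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 2, 2))
  resid_dev <- -2 * ll_old
  null_dev <- -2 * (sum(y) * log(p0) + (n - sum(y)) * log(1 - p0))
  structure(list(site_class = site_class, order = as.integer(order),
                 beta0 = unname(beta[1]), beta1 = unname(beta[2]),
                 se0 = sqrt(vc[1, 1]), se1 = sqrt(vc[2, 2]),
                 null_deviance = null_dev,
                 residual_deviance = min(resid_dev, null_dev),
                 loglik = ll_old, n = n, converged = converged,
                 method = "irls"),
            class = "sr_logistic")
}

#' Predicted probability that FSBI is worse than reference
#'
#' @param model An `sr_logistic` model.
#' @param sf Percent surface fines value(s).
#' @return Probabilities in (0, 1).
#' @export
predict_probability <- function(model, sf) {
  stopifnot(inherits(model, "sr_logistic"))
  if (!isTRUE(model$converged))
    stop_sedbench("model did not converge; predictions unavailable")
  stats::plogis(model$beta0 + model$beta1 * sf)
}

#' Invert a logistic model to an SF benchmark
#'
#' Solves `beta0 + beta1 * SF = logit(p)` for SF: the surface-fines level at
#' which the model predicts probability `p` that FSBI is worse than
#' reference. `p = 0.5` gives SR50, `p = 0.75` gives SR75. Reported
#' benchmarks are rounded to the nearest integer (half away from zero);
#' full precision is retained in `sf_value`.
#'
#' @param model An `sr_logistic` with positive slope.
#' @param p Target probability in (0, 1).
#' @return A list of class `sr_benchmark` with `site_class`, `order`,
#'   `probability`, `sf_value` and `rounded_sf`.
#' @export
#' @examples
#' m <- logistic_model(beta0 = -2.1, beta1 = 0.06)
#' invert_logistic(m, 0.5)$rounded_sf  # 35
invert_logistic <- function(model, p) {
  stopifnot(inherits(model, "sr_logistic"))
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1)
    stop_sedbench("p must be a single probability strictly inside (0, 1)")
  if (!is.finite(model$beta1) || model$beta1 <= 0)
    stop_sedbench("benchmark undefined: slope must be positive ",
                  "(risk must increase with SF)")
  sf <- (stats::qlogis(p) - model$beta0) / model$beta1
  structure(list(site_class = model$site_class, order = model$order,
                 probability = p, sf_value = sf,
                 rounded_sf = as.integer(round_half_up(sf))),
            class = "sr_benchmark")
}

#' @export
print.sr_benchmark <- function(x, ...) {
  cat(sprintf("SR%.0f benchmark: %.2f%% fines (reported %d)\n",
              100 * x$probability, x$sf_value, x$rounded_sf))
  invisible(x)
}

#' Wald confidence interval for the model odds ratio
#'
#' The odds ratio `exp(beta1)` describes how the odds of a
#' worse-than-reference FSBI multiply per 1% increase in SF. The interval
#' is `exp(beta1 +/- z * se1)`.
#'
#' @param model An `sr_logistic` with a finite slope standard error.
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @export
odds_ratio_ci <- function(model, level = 0.95) {
  stopifnot(inherits(model, "sr_logistic"))
  if (!isTRUE(model$converged)) stop_sedbench("model did not converge")
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- if (is.finite(model$se1)) model$se1 else 0
  c(low = exp(model$beta1 - z * se), high = exp(model$beta1 + z * se))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Ranks events by predicted probability, splits them into near-equal
#' groups (deciles by default), and compares observed and expected counts
#' of worse-than-reference outcomes: `sum (O_g - E_g)^2 / (n_g pbar_g (1 -
#' pbar_g))`, referred to chi-square with `groups_used - 2` degrees of
#' freedom. Events with identical predicted probability are never split
#' across groups; groups whose expected count is degenerate (0 or n_g) are
#' merged into a neighbour and `groups_used` records the final count.
#'
#' @param model A converged `sr_logistic`.
#' @param sf,labels The data the model was fitted on.
#' @param groups Target number of groups (default 10); must leave at least
#'   1 degree of freedom after merging (>= 3 groups).
#' @return List with `statistic`, `p_value`, `groups_used` and the
#'   per-group `table` (n, observed, expected).
#' @export
hosmer_lemeshow <- function(model, sf, labels, groups = 10) {
  stopifnot(inherits(model, "sr_logistic"))
  keep <- is.finite(sf) & is.finite(labels)
  sf <- sf[keep]; y <- as.numeric(labels[keep])
  n <- length(y)
  if (groups < 3)
    stop_sedbench("need at least 3 groups for a chi-square test (df >= 1)")
  if (n < 2 * groups)
    stop_sedbench("need at least ", 2 * groups, " events for ", groups,
                  " groups")
  p <- predict_probability(model, sf)
  ord <- order(p)                      # stable: ties keep input order
  p <- p[ord]; y <- y[ord]
  # target boundaries, snapped forward so tied p never straddle a boundary
  cuts <- round(n * seq_len(groups - 1) / groups)
  for (k in seq_along(cuts)) {
    b <- cuts[k]
    while (b >= 1 && b < n && p[b + 1] <= p[b] + 1e-12) b <- b + 1L
    cuts[k] <- b
  }
  cuts <- unique(cuts[cuts < n & cuts >= 1])
  grp <- findInterval(seq_len(n) - 1, cuts) + 1L
  ng <- tapply(rep(1, n), grp, sum)
  og <- tapply(y, grp, sum)
  eg <- tapply(p, grp, sum)
  # merge groups with degenerate expected counts into the previous group
  i <- 1L
  while (i <= length(ng)) {
    if (eg[i] < 1e-12 || ng[i] - eg[i] < 1e-12) {
      j <- if (i > 1) i - 1L else i + 1L
      if (j > length(ng)) break
      ng[j] <- ng[j] + ng[i]; og[j] <- og[j] + og[i]; eg[j] <- eg[j] + eg[i]
      ng <- ng[-i]; og <- og[-i]; eg <- eg[-i]
      if (i > 1) i <- i - 1L
    } else i <- i + 1L
  }
  groups_used <- length(ng)
  if (groups_used < 3)
    stop_sedbench("fewer than 3 usable groups after merging; ",
                  "HL test undefined (df < 1)")
  pbar <- eg / ng
  stat <- sum((og - eg)^2 / (ng * pbar * (1 - pbar)))
  df <- groups_used - 2
  list(statistic = as.numeric(stat),
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       groups_used = as.integer(groups_used),
       table = data.frame(n = as.integer(ng), observed = as.numeric(og),
                          expected = as.numeric(eg)))
}

#' Model fit diagnostics for a stressor-response model
#'
#' Bundles the model chi-square (null minus residual deviance, referred to
#' chi-square with 1 df), the odds ratio and its Wald interval, and the
#' Hosmer-Lemeshow calibration test.
#'
#' @param model A fitted `sr_logistic` (from [fit_logistic()]).
#' @param sf,labels The data behind the fit.
#' @param hl_groups Hosmer-Lemeshow group count, default 10.
#' @param level Confidence level for the odds-ratio interval.
#' @return List of class `sr_diagnostics`.
#' @export
logistic_diagnostics <- function(model, sf, labels, hl_groups = 10,
                                 level = 0.95) {
  stopifnot(inherits(model, "sr_logistic"))
  if (!is.finite(model$null_deviance))
    stop_sedbench("model carries no deviances (was it fitted here?)")
  chi2 <- model$null_deviance - model$residual_deviance
  hl <- tryCatch(hosmer_lemeshow(model, sf, labels, groups = hl_groups),
                 error = function(e) NULL)
  ci <- odds_ratio_ci(model, level = level)
  structure(list(model_chi_square = chi2,
                 chi_square_p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 odds_ratio = exp(model$beta1),
                 or_ci = ci,
                 hl_statistic = if (is.null(hl)) NA_real_ else hl$statistic,
                 hl_p = if (is.null(hl)) NA_real_ else hl$p_value,
                 hl_groups = if (is.null(hl)) NA_integer_ else hl$groups_used),
            class = "sr_diagnostics")
}
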