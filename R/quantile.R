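# Reach-specific SF reference benchmarks: linear tau-quantile regression of
# SF on bankfull width within a stream order, fitted by minimising the
# pinball (check) loss sum_i rho_tau(sf_i - a - b * bw_i).

pinball_loss <- function(resid, tau) {
  sum(resid * (tau - (resid < 0)))
}

#' Construct a quantile-regression benchmark model
#'
#' Builds a `sf_quantile_model` from known coefficients, e.g. published
#' statewide coefficient sets, without refitting.
#'
#' @param intercept Intercept, percent fines.
#' @param slope Slope, percent fines per metre of bankfull width.
#' @param order Strahler stream order (1-4) the model applies to.
#' @param tau Quantile level in (0, 1); 0.75 for the upper-bound reference
#'   benchmark.
#' @param n Number of reference events the model was fitted on (may be NA).
#' @return An object of class `sf_quantile_model`.
#' @seealso [fit_sf_quantile()], [predict_sf_ref()]
#' @export
quantile_model <- function(intercept, slope, order = NA_integer_,
                           tau = 0.75, n = NA_integer_) {
  stopifnot(is.finite(intercept), is.finite(slope), tau > 0, tau < 1)
  structure(list(order = as.integer(order), tau = tau,
                 intercept = as.numeric(intercept),
                 slope = as.numeric(slope), n = as.integer(n),
                 loss = NA_real_, method = "supplied"),
            class = "sf_quantile_model")
}

#' @export
print.sf_quantile_model <- function(x, ...) {
  cat(sprintf("SF quantile-regression model (tau = %.2f%s)\n", x$tau,
              if (is.na(x$order)) "" else paste0(", order ", x$order)))
  cat(sprintf("  SF_ref = %.5f %s %.5f * BW   [n = %s, %s]\n",
              x$intercept, ifelse(x$slope < 0, "-", "+"), abs(x$slope),
              ifelse(is.na(x$n), "?", x$n), x$method))
  invisible(x)
}

# Exhaustive LP-vertex search: an optimal pinball-loss line interpolates two
# data points, so evaluating every pair is exact. Ties (flat LP optima) are
# broken by smallest |slope| then smallest intercept so fits are
# reproducible.
fit_quantile_pairs <- function(bw, sf, tau, tie_tol = 1e-9) {
  n <- length(bw)
  best <- NULL
  best_loss <- Inf
  cand <- list()
  for (i in seq_len(n - 1)) {
    dx <- bw[(i + 1):n] - bw[i]
    ok <- which(abs(dx) > 1e-12)
    for (k in ok) {
      j <- i + k
      b <- (sf[j] - sf[i]) / (bw[j] - bw[i])
      a <- sf[i] - b * bw[i]
      loss <- pinball_loss(sf - a - b * bw, tau)
      if (loss < best_loss - tie_tol) {
        best_loss <- loss
        cand <- list(c(a, b))
      } else if (loss <= best_loss + tie_tol) {
        cand[[length(cand) + 1L]] <- c(a, b)
      }
    }
  }
  if (!length(cand)) stop_sedbench("degenerate data: no valid point pairs")
  m <- do.call(rbind, cand)
  m <- m[order(abs(m[, 2]), m[, 1]), , drop = FALSE]
  list(intercept = m[1, 1], slope = m[1, 2], loss = best_loss)
}

# Iteratively reweighted least squares approximation for large n (the check
# loss is smoothed by an epsilon floor that is annealed), then polished to
# an exact LP vertex by a pair search among the points nearest the fitted
# line, scoring candidates on the full-data loss.
fit_quantile_irls <- function(bw, sf, tau, polish_k = 40L) {
  X <- cbind(1, bw)
  beta <- stats::coef(stats::lm.fit(X, sf))
  for (eps in c(1e-2, 1e-3, 1e-4, 1e-6, 1e-8)) {
    for (it in 1:50) {
      r <- sf - X %*% beta
      w <- ifelse(r >= 0, tau, 1 - tau) / pmax(abs(r), eps)
      new <- stats::coef(stats::lm.wfit(X, sf, as.numeric(w)))
      if (max(abs(new - beta)) < 1e-10) { beta <- new; break }
      beta <- new
    }
  }
  r <- as.numeric(sf - X %*% beta)
  near <- order(abs(r))[seq_len(min(polish_k, length(bw)))]
  pairs <- utils::combn(near, 2)
  best <- list(intercept = beta[1], slope = beta[2],
               loss = pinball_loss(r, tau))
  cand <- list(c(beta[1], beta[2]))
  best_loss <- best$loss
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    if (abs(bw[i] - bw[j]) < 1e-12) next
    b <- (sf[j] - sf[i]) / (bw[j] - bw[i])
    a <- sf[i] - b * bw[i]
    loss <- pinball_loss(sf - a - b * bw, tau)
    if (loss < best_loss - 1e-9) {
      best_loss <- loss; cand <- list(c(a, b))
    } else if (loss <= best_loss + 1e-9) {
      cand[[length(cand) + 1L]] <- c(a, b)
    }
  }
  m <- do.call(rbind, cand)
  m <- m[order(abs(m[, 2]), m[, 1]), , drop = FALSE]
  list(intercept = m[1, 1], slope = m[1, 2], loss = best_loss)
}

#' Fit the SF reference quantile-regression model
#'
#' Fits `SF = intercept + slope * BW` at quantile level `tau` by minimising
#' the pinball loss. For n <= 200 the fit is an exhaustive search over all
#' lines through point pairs (exact); above that, iteratively reweighted
#' least squares followed by a local vertex polish. Ties among optimal
#' lines are broken by smallest absolute slope, then smallest intercept.
#'
#' @param bw Bankfull widths (m), all > 0 and not all equal.
#' @param sf Percent surface fines, same length as `bw`.
#' @param tau Quantile level, default 0.75 (upper bound expected under
#'   reference conditions).
#' @param order Optional Strahler order recorded on the model.
#' @param min_n Minimum number of events required (default 10).
#' @param method `"auto"` (exhaustive up to n = 200, IRLS above),
#'   `"exact"` or `"irls"`.
#' @return An `sf_quantile_model` with the attained pinball loss in `$loss`.
#' @export
fit_sf_quantile <- function(bw, sf, tau = 0.75, order = NA_integer_,
                            min_n = 10, method = c("auto", "exact", "irls")) {
  method <- match.arg(method)
  stopifnot(length(bw) == length(sf), tau > 0, tau < 1)
  keep <- is.finite(bw) & is.finite(sf)
  bw <- bw[keep]; sf <- sf[keep]
  if (length(bw) < min_n)
    stop_sedbench("need at least ", min_n, " events to fit, got ", length(bw))
  if (any(bw <= 0)) stop_sedbench("bankfull widths must be positive")
  if (max(bw) - min(bw) < 1e-12)
    stop_sedbench("degenerate bankfull widths (all equal); slope not identifiable")
  exact <- switch(method, auto = length(bw) <= 200, exact = TRUE,
                  irls = FALSE)
  fit <- if (exact) fit_quantile_pairs(bw, sf, tau)
         else fit_quantile_irls(bw, sf, tau)
  structure(list(order = as.integer(order), tau = tau,
                 intercept = fit$intercept, slope = fit$slope,
                 n = length(bw), loss = fit$loss,
                 method = if (exact) "exhaustive-pairs"
                          else "irls+vertex-polish"),
            class = "sf_quantile_model")
}

#' Reach-specific SF reference benchmark
#'
#' Evaluates the quantile-regression line at a reach's bankfull width and
#' clips the prediction to the valid percentage range \[0, 100\] (the fitted
#' lines go negative on extrapolation to very wide channels).
#'
#' @param model An `sf_quantile_model`.
#' @param bw Bankfull width(s) in metres, > 0.
#' @return Numeric SF_ref value(s), percent fines in \[0, 100\].
#' @export
#' @examples
#' m <- quantile_model(intercept = 47.73073, slope = -3.22255, order = 1)
#' predict_sf_ref(m, 5)
predict_sf_ref <- function(model, bw) {
  stopifnot(inherits(model, "sf_quantile_model"))
  if (any(!is.finite(bw)) || any(bw <= 0))
    stop_sedbench("bankfull width must be positive")
  pmin(pmax(model$intercept + model$slope * bw, 0), 100)
}

#' FSBI reference benchmark for a site class
#'
#' The lower percentile (default 25th, Hyndman-Fan type 7) of FSBI among
#' reference events of one site class; FSBI below this value is "worse than
#' reference".
#'
#' @param fsbi FSBI values of reference events in the class.
#' @param probs Percentile as a fraction, default 0.25.
#' @param min_n Minimum number of events required (default 10).
#' @return A single numeric FSBI_ref value.
#' @export
compute_fsbi_ref <- function(fsbi, probs = 0.25, min_n = 10) {
  fsbi <- fsbi[is.finite(fsbi)]
  if (length(fsbi) < min_n)
    stop_sedbench("need at least ", min_n, " reference FSBI values, got ",
                  length(fsbi))
  quantile7(fsbi, probs)
}
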