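# Association between SF benchmark status and biological condition:
# design-weighted relative risk and reference-site false-positive rates.

#' Rate each event's SF and biological condition
#'
#' SF condition is `"poor"` when measured SF strictly exceeds the
#' reach-specific SF reference benchmark predicted from bankfull width
#' (achievement at exact equality). Biological condition is `"poor"` when
#' the chosen indicator falls strictly below its benchmark: FSBI below the
#' class FSBI_ref, or a user-supplied cutoff for SMI2 / O-E style indices.
#'
#' @param events Data frame with `event_id`, `site_class`, `order`,
#'   `bankfull_width_m`, `sf`, the indicator column (`fsbi`, `smi2` or
#'   `oe`), and optionally `weight` (default 1).
#' @param bset A `benchmark_set` supplying SF quantile models and FSBI_ref.
#' @param bio_indicator One of `"fsbi"`, `"smi2"`, `"oe"`.
#' @param bio_benchmark Benchmark for `smi2`/`oe`: a single value or a
#'   named vector by site class. Ignored for `fsbi` (FSBI_ref is used).
#' @return Data frame of class `condition_flags`: `event_id`, `sf_status`,
#'   `bio_status`, `weight`, plus the benchmarks used. Events with missing
#'   ingredients are dropped with a count reported in
#'   `attr(, "n_excluded")`.
#' @export
condition_flags <- function(events, bset,
                            bio_indicator = c("fsbi", "smi2", "oe"),
                            bio_benchmark = NULL) {
  bio_indicator <- match.arg(bio_indicator)
  stopifnot(inherits(bset, "benchmark_set"))
  req <- c("event_id", "site_class", "order", "bankfull_width_m", "sf",
           bio_indicator)
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop_sedbench("events missing column(s): ", paste(miss, collapse = ", "))
  ev <- events
  ev$site_class <- normalize_site_class(ev$site_class)
  if (is.null(ev$weight)) ev$weight <- 1
  if (any(is.finite(ev$weight) & ev$weight <= 0))
    stop_sedbench("survey weights must be positive")

  n0 <- nrow(ev)
  sf_ref <- rep(NA_real_, n0)
  for (od in 1:4) {
    m <- bset$quantile_models[[as.character(od)]]
    sel <- which(ev$order == od & is.finite(ev$bankfull_width_m) &
                   ev$bankfull_width_m > 0)
    if (!is.null(m) && length(sel))
      sf_ref[sel] <- predict_sf_ref(m, ev$bankfull_width_m[sel])
  }

  bio_val <- ev[[bio_indicator]]
  if (bio_indicator == "fsbi") {
    bio_ref <- unname(bset$fsbi_ref[ev$site_class])
  } else {
    if (is.null(bio_benchmark))
      stop_sedbench("bio_benchmark is required for indicator ", bio_indicator)
    bio_ref <- if (length(bio_benchmark) == 1 && is.null(names(bio_benchmark)))
      rep(as.numeric(bio_benchmark), n0)
    else unname(as.numeric(bio_benchmark[ev$site_class]))
  }

  ok <- is.finite(sf_ref) & is.finite(ev$sf) & is.finite(bio_val) &
    is.finite(bio_ref) & is.finite(ev$weight)
  out <- data.frame(
    event_id = as.character(ev$event_id[ok]),
    sf_status = ifelse(ev$sf[ok] > sf_ref[ok], "poor", "good"),
    bio_status = ifelse(bio_val[ok] < bio_ref[ok], "poor", "good"),
    weight = as.numeric(ev$weight[ok]),
    sf_ref = sf_ref[ok], bio_ref = bio_ref[ok],
    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n0 - nrow(out)
  attr(out, "bio_indicator") <- bio_indicator
  class(out) <- c("condition_flags", class(out))
  out
}

#' Design-weighted relative risk
#'
#' The ratio of two weighted conditional probabilities: P(bio poor | SF
#' poor) / P(bio poor | SF good), with survey weights (inverse inclusion
#' probabilities). The 95% interval comes from Taylor linearization of
#' log(RR) treating the design as single-stage with known weights:
#' `var(log p) = sum w_i^2 (y_i - p)^2 / (sum w)^2 / p^2` per stratum. RR
#' and its interval are invariant to rescaling all weights.
#'
#' @param flags A `condition_flags` data frame (or any data frame with
#'   `sf_status`, `bio_status`, `weight`).
#' @param level Confidence level, default 0.95.
#' @return Object of class `rr_estimate`: `rr`, `ci`, `level`, weighted
#'   2x2 `cells`, conditional probabilities and `n_events`.
#' @export
relative_risk <- function(flags, level = 0.95) {
  stopifnot(all(c("sf_status", "bio_status") %in% names(flags)))
  w <- flags$weight %||% rep(1, nrow(flags))
  if (is.null(flags$weight)) flags$weight <- w
  if (any(!is.finite(w)) || any(w <= 0))
    stop_sedbench("weights must be positive and finite")
  poor_sf <- flags$sf_status == "poor"
  poor_bio <- flags$bio_status == "poor"
  if (!any(poor_sf) || !any(!poor_sf))
    stop_sedbench("both SF strata (good and poor) must be non-empty")

  cells <- c(poor_poor = sum(w[poor_sf & poor_bio]),
             good_poor = sum(w[poor_sf & !poor_bio]),
             poor_good = sum(w[!poor_sf & poor_bio]),
             good_good = sum(w[!poor_sf & !poor_bio]))
  p1 <- cells[["poor_poor"]] / (cells[["poor_poor"]] + cells[["good_poor"]])
  p0 <- cells[["poor_good"]] / (cells[["poor_good"]] + cells[["good_good"]])
  if (p0 <= 0)
    stop_sedbench("relative risk undefined: no poor biological condition ",
                  "in the SF-good stratum (zero denominator probability)")
  rr <- p1 / p0

  var_log_p <- function(sel, p) {
    wi <- w[sel]; yi <- as.numeric(poor_bio[sel])
    sum(wi^2 * (yi - p)^2) / sum(wi)^2 / p^2
  }
  se_log <- sqrt(var_log_p(poor_sf, p1) + var_log_p(!poor_sf, p0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- c(low = rr * exp(-z * se_log), high = rr * exp(z * se_log))

  structure(list(rr = unname(rr), ci = ci, level = level,
                 p_poor_given_poor = unname(p1),
                 p_poor_given_good = unname(p0),
                 cells = cells, se_log_rr = se_log,
                 n_events = nrow(flags),
                 ci_method = "taylor-linearized log(RR), z = normal"),
            class = "rr_estimate")
}

#' @export
print.rr_estimate <- function(x, ...) {
  cat(sprintf("Relative risk: %.2f (%.0f%% CI %.2f-%.2f), n = %d events\n",
              x$rr, 100 * x$level, x$ci[["low"]], x$ci[["high"]], x$n_events))
  cat(sprintf("  P(bio poor | SF poor) = %.4f, P(bio poor | SF good) = %.4f\n",
              x$p_poor_given_poor, x$p_poor_given_good))
  invisible(x)
}

#' False-positive rates on reference sites
#'
#' Among reference-labelled events, the share failing the SF benchmark, the
#' share failing the FSBI benchmark, and the share the framework rates
#' `"likely"` (both failed). Because a `"likely"` rating requires both
#' failures, the framework rate can never exceed either marginal rate.
#'
#' @param events Reference events with `site_class`, `order`,
#'   `bankfull_width_m`, `sf`, `fsbi`. If a `disturbance` column is
#'   present, only rows labelled `"reference"` are used.
#' @param bset A `benchmark_set`.
#' @return List with percentages `fp_sf`, `fp_fsbi`, `fp_framework` and
#'   `n` (assessable reference events).
#' @export
false_positive_rates <- function(events, bset) {
  stopifnot(inherits(bset, "benchmark_set"))
  if ("disturbance" %in% names(events))
    events <- events[which(events$disturbance == "reference"), , drop = FALSE]
  if (!nrow(events)) stop_sedbench("no reference events supplied")
  res <- assess_dataset(events, bset)
  r <- res$ratings
  if (!nrow(r)) stop_sedbench("no assessable reference events")
  list(fp_sf = 100 * mean(!r$sf_achieved),
       fp_fsbi = 100 * mean(!r$fsbi_achieved),
       fp_framework = 100 * mean(r$rating == "likely"),
       n = nrow(r))
}
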