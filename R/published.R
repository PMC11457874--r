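# Published Idaho benchmark coefficient sets, shipped so the benchmarks can
# be applied to new sample events without access to the original statewide
# BURP calibration data.

#' Published Idaho SF reference quantile-regression models
#'
#' The statewide tau = 0.75 quantile-regression coefficients relating
#' percent surface fines (<2.5 mm) to bankfull width within each Strahler
#' order, fitted to BURP reference sites. Use with [predict_sf_ref()] to
#' obtain reach-specific SF reference benchmarks.
#'
#' @return Named list of `sf_quantile_model` objects, one per order 1-4.
#' @export
#' @examples
#' predict_sf_ref(idaho_sf_ref_models()[["1"]], bw = 5)
idaho_sf_ref_models <- function() {
  coefs <- data.frame(
    order = 1:4,
    intercept = c(47.73073, 41.62932, 34.97105, 29.54360),
    slope = c(-3.22255, -2.49803, -1.24737, -0.62823))
  out <- lapply(seq_len(4), function(i)
    quantile_model(coefs$intercept[i], coefs$slope[i], order = coefs$order[i],
                   tau = 0.75))
  stats::setNames(out, as.character(1:4))
}

#' Published Idaho FSBI reference benchmarks
#'
#' The 25th-percentile FSBI among BURP reference sites within each site
#' class: FSBI below the class value is rated worse than reference.
#'
#' @return Named numeric vector by site class.
#' @export
idaho_fsbi_ref <- function() {
  c(mountains = 140, foothills = 76, ppbv = 20)
}

#' Published Idaho stressor-response logistic coefficients
#'
#' Per site class x stream order logistic regression coefficients for the
#' probability that FSBI is worse than reference as a function of percent
#' surface fines, with sample sizes and reported SR50/SR75 benchmarks. The
#' mountains order-2 intercept was printed without a sign in the source
#' coefficient table; it is stored as negative here (every fitted intercept
#' is negative, and only the negative sign reproduces the reported
#' benchmarks on inversion).
#'
#' @return Data frame with columns `site_class`, `order`, `n`, `sr50`,
#'   `sr75`, `beta0`, `se0`, `beta1`, `se1`.
#' @seealso [logistic_model()], [invert_logistic()]
#' @export
idaho_sr_models <- function() {
  data.frame(
    site_class = rep(c("mountains", "foothills", "ppbv"), each = 4),
    order = rep(1:4, times = 3),
    n = c(175, 392, 315, 122, 503, 1320, 803, 158, 202, 483, 452, 205),
    sr50 = c(34, 37, 42, 31, 35, 41, 34, 28, 57, 63, 51, 40),
    sr75 = c(58, 55, 71, 53, 52, 61, 56, 47, 73, 89, 69, 53),
    beta0 = c(-1.45, -2.18, -1.54, -1.07, -2.1, -1.98, -1.6, -1.5,
              -3.75, -2.5, -2.9, -3.05),
    se0 = c(0.2, 0.13, 0.13, 0.29, 0.43, 0.25, 0.22, 0.32,
            0.5, 0.24, 0.27, 0.41),
    beta1 = c(0.04, 0.06, 0.04, 0.04, 0.06, 0.05, 0.05, 0.05,
              0.07, 0.04, 0.06, 0.08),
    se1 = c(0.006, 0.005, 0.006, 0.02, 0.01, 0.006, 0.007, 0.01,
            0.01, 0.005, 0.006, 0.01),
    stringsAsFactors = FALSE)
}

#' Assemble the published Idaho benchmarks into a benchmark set
#'
#' Bundles [idaho_sf_ref_models()], [idaho_fsbi_ref()] and
#' [idaho_sr_models()] into a `benchmark_set` so the published benchmarks
#' can be applied directly to new sample events with [assess_dataset()],
#' [condition_flags()] and [false_positive_rates()].
#'
#' @return A `benchmark_set` whose models carry method `"supplied"`; fit
#'   diagnostics are not part of the published coefficient set and are NA.
#' @export
#' @examples
#' bset <- idaho_benchmark_set()
#' ev <- data.frame(event_id = "e1", site_class = "mountains", order = 1,
#'                  bankfull_width_m = 4, sf = 22, fsbi = 180)
#' assess_dataset(ev, bset)$ratings$rating
idaho_benchmark_set <- function() {
  sr <- idaho_sr_models()
  models <- list()
  for (i in seq_len(nrow(sr)))
    models[[paste(sr$site_class[i], sr$order[i], sep = ".")]] <-
      logistic_model(sr$beta0[i], sr$beta1[i], se0 = sr$se0[i],
                     se1 = sr$se1[i], site_class = sr$site_class[i],
                     order = sr$order[i], n = sr$n[i])
  tab <- data.frame(site_class = sr$site_class, order = sr$order, n = sr$n,
                    n_worse = NA_integer_, sr50 = sr$sr50, sr75 = sr$sr75,
                    sr50_exact = NA_real_, sr75_exact = NA_real_,
                    beta0 = sr$beta0, se0 = sr$se0, beta1 = sr$beta1,
                    se1 = sr$se1, chi_square = NA_real_,
                    chi_square_p = NA_real_, odds_ratio = exp(sr$beta1),
                    or_low = NA_real_, or_high = NA_real_,
                    hl_statistic = NA_real_, hl_p = NA_real_,
                    hl_groups = NA_integer_, available = TRUE, note = "",
                    stringsAsFactors = FALSE)
  structure(list(quantile_models = idaho_sf_ref_models(),
                 fsbi_ref = idaho_fsbi_ref(),
                 fsbi_ref_n = stats::setNames(rep(NA_integer_, 3),
                                              site_classes()),
                 sr = tab, sr_models = models,
                 meta = list(tau = 0.75, fsbi_percentile = 0.25,
                             percentile_method = "type7",
                             source = "published Idaho coefficient set")),
            class = "benchmark_set")
}
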