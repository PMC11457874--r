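# Synthetic BURP-style monitoring data with known generating truth, so the
# whole benchmark pipeline can be validated by parameter recovery.

#' Default synthetic taxon pool
#'
#' Forty Northwest-US stream macroinvertebrate genera with synthetic
#' sediment-sensitivity scores and logistic occupancy parameters. Taxa with
#' positive sensitivity scores have non-positive occupancy slopes in SF, so
#' sensitive taxa drop out as fines increase — the mechanism behind the
#' wedge-shaped FSBI response. Scores are integers in the same 0-13 range
#' as published FSBI taxon scores; they are demonstration values, not the
#' published table.
#'
#' @return Data frame with columns `taxon`, `score`, `occ_intercept`,
#'   `occ_slope` (log-odds of occurrence per percent SF).
#' @export
default_taxon_pool <- function() {
  data.frame(
    taxon = c("Drunella doddsii", "Drunella coloradensis", "Epeorus",
              "Rhithrogena", "Cinygmula", "Caudatella", "Yoraperla",
              "Megarcys", "Doroneuria", "Sweltsa", "Neothremma",
              "Parapsyche", "Arctopsyche", "Glossosoma", "Dicosmoecus",
              "Oligophlebodes", "Ameletus", "Heterlimnius", "Narpus",
              "Cleptelmis",
              "Baetis", "Ephemerella", "Serratella", "Hydropsyche",
              "Brachycentrus", "Lepidostoma", "Micrasema", "Optioservus",
              "Zaitzevia", "Antocha",
              "Chironomus", "Oligochaeta", "Simulium", "Tricorythodes",
              "Physa", "Pisidium", "Hyalella", "Sphaerium", "Cricotopus",
              "Corixidae"),
    score = c(13, 12, 10, 10, 8, 11, 9, 10, 9, 7, 8, 9, 7, 6, 6, 7, 6, 6,
              6, 6,
              2, 4, 4, 3, 5, 4, 5, 3, 3, 2,
              0, 0, 1, 1, 0, 0, 0, 0, 1, 0),
    occ_intercept = c(1.4, 1.3, 1.2, 1.3, 1.2, 1.1, 1.2, 1.0, 1.1, 1.3,
                      1.0, 1.1, 1.2, 1.2, 1.0, 0.9, 1.1, 1.2, 1.0, 0.9,
                      1.5, 1.2, 1.1, 1.2, 1.0, 1.1, 1.0, 1.3, 1.2, 1.0,
                      0.0, 0.2, 0.8, 0.2, -0.5, -0.3, -0.2, -0.5, 0.3, -1.0),
    occ_slope = c(-0.060, -0.055, -0.050, -0.055, -0.045, -0.060, -0.050,
                  -0.055, -0.050, -0.040, -0.045, -0.050, -0.040, -0.035,
                  -0.040, -0.045, -0.035, -0.035, -0.040, -0.035,
                  -0.010, -0.025, -0.020, -0.015, -0.025, -0.020, -0.025,
                  -0.015, -0.015, -0.010,
                  0.012, 0.010, 0.000, 0.000, 0.012, 0.010, 0.010, 0.008,
                  0.000, 0.010),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic monitoring-data generator
#'
#' Defines the study conditions emulated by [simulate_events()]: three
#' ecoregion site classes, Strahler orders 1-4, bankfull width lognormal
#' within order, SF generated as a logit-normal deviation around an
#' order/BW-dependent quantile line (so the configured line *is* the true
#' 75th percentile under reference), occurrence-only taxa with logistic
#' occupancy in SF, and a reference/stress/ambient disturbance mix.
#'
#' Defaults mirror a statewide wadable-stream bioassessment program: class
#' and order mixing proportions follow the relative cell sizes of the
#' Idaho calibration dataset, the generating quantile lines are the
#' published Idaho coefficients, and the logit-scale noise (0.7) and
#' stress shift (+1.0) reproduce reference medians near 29% and stress
#' medians near 48% SF in first-order streams.
#'
#' @param n_sites Number of sites (one sample event each).
#' @param class_proportions Named fractions over
#'   mountains/foothills/ppbv, summing to 1.
#' @param order_proportions Fractions over orders 1-4, summing to 1.
#' @param bw_log_mean_by_order Mean log bankfull width (log metres) per
#'   order.
#' @param bw_log_sd Common log-scale SD of bankfull width.
#' @param bw_range_by_order 4 x 2 matrix of per-order bankfull-width
#'   truncation bounds (m). Wadable 1st-4th order streams have physically
#'   bounded widths; truncation also keeps the generating quantile line
#'   positive over the whole support.
#' @param sf_quantile_truth Data frame `order`, `intercept`, `slope`: the
#'   generating 75th-percentile SF line per order (percent, percent/m).
#' @param sf_noise_scale Logit-scale SD of within-order SF variation (0 or
#'   larger).
#' @param taxon_pool Data frame as [default_taxon_pool()]; scores must be
#'   non-negative and score-positive taxa must have occupancy slopes at or
#'   below zero.
#' @param weight_scheme `"equal"` or `"order_stratified"`.
#' @param disturbance_mix Named fractions over reference/stress/ambient,
#'   summing to 1.
#' @param stress_shift,ambient_shift Logit-scale SF shifts applied to
#'   stress- and ambient-labelled events (reference events are unshifted).
#' @param class_occ_shift Named per-class shift added to taxon occupancy
#'   intercepts (site classes differ in taxon richness).
#' @param order_extent Relative stream extent per order, used by the
#'   order-stratified weight scheme.
#' @param seed Integer master seed; expanded into per-operation
#'   substreams.
#' @return Validated list of class `sim_config`.
#' @export
simulation_config <- function(
    n_sites = 600,
    class_proportions = c(mountains = 0.20, foothills = 0.54, ppbv = 0.26),
    order_proportions = c(0.17, 0.43, 0.31, 0.09),
    bw_log_mean_by_order = log(c(2.5, 4, 7, 12)),
    bw_log_sd = 0.5,
    bw_range_by_order = cbind(lower = c(0.5, 1.0, 1.5, 2.0),
                              upper = c(12, 14, 24, 40)),
    sf_quantile_truth = data.frame(
      order = 1:4,
      intercept = c(47.73073, 41.62932, 34.97105, 29.54360),
      slope = c(-3.22255, -2.49803, -1.24737, -0.62823)),
    sf_noise_scale = 0.7,
    taxon_pool = default_taxon_pool(),
    weight_scheme = c("equal", "order_stratified"),
    disturbance_mix = c(reference = 0.10, stress = 0.10, ambient = 0.80),
    stress_shift = 1.0,
    ambient_shift = 0.5,
    class_occ_shift = c(mountains = 0.5, foothills = 0.0, ppbv = -1.5),
    order_extent = c(0.45, 0.30, 0.17, 0.08),
    seed = 1L) {
  weight_scheme <- match.arg(weight_scheme)
  stopifnot(n_sites >= 1)
  check_props <- function(p, k, what) {
    if (length(p) != k || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop_sedbench(what, " must be ", k,
                    " non-negative fractions summing to 1")
  }
  check_props(class_proportions, 3, "class_proportions")
  check_props(order_proportions, 4, "order_proportions")
  check_props(disturbance_mix, 3, "disturbance_mix")
  if (is.null(names(class_proportions)))
    names(class_proportions) <- site_classes()
  if (is.null(names(disturbance_mix)))
    names(disturbance_mix) <- c("reference", "stress", "ambient")
  bw_range_by_order <- as.matrix(bw_range_by_order)
  stopifnot(bw_log_sd > 0, sf_noise_scale >= 0,
            nrow(bw_range_by_order) == 4, ncol(bw_range_by_order) == 2,
            all(bw_range_by_order[, 1] > 0),
            all(bw_range_by_order[, 2] > bw_range_by_order[, 1]),
            length(bw_log_mean_by_order) == 4,
            all(c("order", "intercept", "slope") %in%
                  names(sf_quantile_truth)),
            nrow(sf_quantile_truth) == 4)
  if (!is.data.frame(taxon_pool) || nrow(taxon_pool) == 0)
    stop_sedbench("taxon pool must be a non-empty data frame")
  stopifnot(all(c("taxon", "score", "occ_intercept", "occ_slope") %in%
                  names(taxon_pool)))
  if (any(taxon_pool$score < 0))
    stop_sedbench("sensitivity scores must be >= 0")
  if (any(taxon_pool$score > 0 & taxon_pool$occ_slope > 0))
    stop_sedbench("score-positive (sensitive) taxa must have occupancy ",
                  "SF-slopes <= 0")
  structure(list(
    n_sites = as.integer(n_sites),
    class_proportions = class_proportions,
    order_proportions = order_proportions,
    bw_log_mean_by_order = bw_log_mean_by_order,
    bw_log_sd = bw_log_sd,
    bw_range_by_order = bw_range_by_order,
    sf_quantile_truth = sf_quantile_truth,
    sf_noise_scale = sf_noise_scale,
    taxon_pool = taxon_pool,
    weight_scheme = weight_scheme,
    disturbance_mix = disturbance_mix,
    stress_shift = stress_shift,
    ambient_shift = ambient_shift,
    class_occ_shift = class_occ_shift,
    order_extent = order_extent,
    seed = as.integer(seed)), class = "sim_config")
}

# Truncated lognormal bankfull widths (inverse-CDF draw, no rejection).
sim_bw_values <- function(ord, cfg) {
  mu <- cfg$bw_log_mean_by_order[ord]
  lo <- cfg$bw_range_by_order[ord, 1]
  hi <- cfg$bw_range_by_order[ord, 2]
  p_lo <- stats::plnorm(lo, mu, cfg$bw_log_sd)
  p_hi <- stats::plnorm(hi, mu, cfg$bw_log_sd)
  u <- stats::runif(length(ord), p_lo, p_hi)
  stats::qlnorm(u, mu, cfg$bw_log_sd)
}

# Generating SF model: the configured per-order line q(BW) is the exact
# tau = 0.75 quantile of reference SF because
#   SF = 100 * plogis(qlogis(q/100) + shift + sigma * (Z - qnorm(0.75)))
# is a monotone transform of Z ~ N(0,1) that passes through q at the 75th
# percentile when shift = 0. The line is clipped into (0.5, 99.5)% before
# the logit so percentages stay valid.
sim_sf_values <- function(q75, shift, sigma, z) {
  qc <- pmin(pmax(q75, 0.5), 99.5)
  100 * stats::plogis(stats::qlogis(qc / 100) + shift +
                        sigma * (z - stats::qnorm(0.75)))
}

# Exact P(FSBI < threshold | SF, class) by dynamic-programming convolution
# of independent Bernoulli taxa with integer scores.
fsbi_worse_prob <- function(sf, class_shift, pool, threshold) {
  scores <- pool$score
  if (any(scores != round(scores)))
    stop_sedbench("exact FSBI distribution needs integer scores")
  p_occ <- stats::plogis(pool$occ_intercept + class_shift +
                           pool$occ_slope * sf)
  smax <- sum(scores)
  dist <- c(1, rep(0, smax))
  for (j in seq_along(scores)) {
    s <- scores[j]; p <- p_occ[j]
    if (s == 0 || p == 0) next
    shifted <- c(rep(0, s), dist[seq_len(smax + 1 - s)])
    dist <- dist * (1 - p) + shifted * p
  }
  upper <- ceiling(threshold) - 1  # FSBI strictly below the threshold
  if (upper < 0) return(0)
  sum(dist[seq_len(min(upper, smax) + 1)])
}

# SF at which P(FSBI worse | SF) crosses p, from the generating model.
invert_fsbi_worse <- function(p, class_shift, pool, threshold) {
  f <- function(sf) fsbi_worse_prob(sf, class_shift, pool, threshold) - p
  if (f(0) >= 0 || f(100) <= 0) return(NA_real_)
  stats::uniroot(f, c(0, 100), tol = 1e-8)$root
}

draw_fsbi <- function(sf, class_shift, pool) {
  n <- length(sf)
  eta <- outer(sf, pool$occ_slope) +
    rep(pool$occ_intercept, each = n) + class_shift
  present <- matrix(stats::runif(n * nrow(pool)), n) < stats::plogis(eta)
  as.numeric(present %*% pool$score)
}

#' Simulate a BURP-style monitoring dataset with known truth
#'
#' Draws one sample event per site: site class, Strahler order, bankfull
#' width (lognormal within order), disturbance label, SF (logit-normal
#' around the order's generating quantile line, shifted upward for stress
#' and ambient events), taxa presence (independent Bernoulli with logistic
#' occupancy in SF) and the resulting FSBI, plus survey weights. The
#' returned truth records the generating quantile lines exactly, the
#' per-class reference FSBI_ref (computed from the generating model by a
#' dedicated Monte-Carlo substream, n = 20000/class, independent of the
#' emitted events) and the per class x order SF values at 50% and 75%
#' probability of a worse-than-reference FSBI (exact, by convolution of
#' the integer taxon scores).
#'
#' @param config A `sim_config`, see [simulation_config()].
#' @param compute_truth Compute the generating-truth summaries (default
#'   `TRUE`; the event draw itself is unaffected).
#' @return List of class `sedbench_simulation`: `events` (data frame),
#'   `occurrences` (event_id x taxon), `truth`, and the `config`.
#' @export
simulate_events <- function(config, compute_truth = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_sites

  set.seed(substream_seed(cfg$seed, 1))
  cls <- sample(names(cfg$class_proportions), n, replace = TRUE,
                prob = cfg$class_proportions)
  ord <- sample(1:4, n, replace = TRUE, prob = cfg$order_proportions)
  bw <- sim_bw_values(ord, cfg)

  set.seed(substream_seed(cfg$seed, 2))
  dist_lab <- sample(names(cfg$disturbance_mix), n, replace = TRUE,
                     prob = cfg$disturbance_mix)
  shift <- c(reference = 0, stress = cfg$stress_shift,
             ambient = cfg$ambient_shift)[dist_lab]

  set.seed(substream_seed(cfg$seed, 3))
  tr <- cfg$sf_quantile_truth
  q75 <- tr$intercept[match(ord, tr$order)] +
    tr$slope[match(ord, tr$order)] * bw
  sf <- sim_sf_values(q75, shift, cfg$sf_noise_scale, stats::rnorm(n))

  set.seed(substream_seed(cfg$seed, 4))
  pool <- cfg$taxon_pool
  cls_shift <- cfg$class_occ_shift[cls]
  eta <- outer(sf, pool$occ_slope) +
    rep(pool$occ_intercept, each = n) + cls_shift
  present <- matrix(stats::runif(n * nrow(pool)), n) < stats::plogis(eta)
  fsbi <- as.numeric(present %*% pool$score)

  ids <- sprintf("EV%05d", seq_len(n))
  events <- data.frame(event_id = ids, comid = sprintf("C%05d", seq_len(n)),
                       site_class = cls, order = ord,
                       bankfull_width_m = bw, disturbance = dist_lab,
                       sf = sf, fsbi = fsbi, stringsAsFactors = FALSE)
  events$weight <- simulate_weights(events, cfg$weight_scheme,
                                    order_extent = cfg$order_extent)

  occ <- which(present, arr.ind = TRUE)
  occurrences <- data.frame(event_id = ids[occ[, 1]],
                            taxon = pool$taxon[occ[, 2]],
                            stringsAsFactors = FALSE)
  occurrences <- occurrences[order(occ[, 1], occ[, 2]), , drop = FALSE]
  rownames(occurrences) <- NULL

  truth <- if (compute_truth) simulation_truth(cfg) else NULL
  structure(list(events = events, occurrences = occurrences, truth = truth,
                 config = cfg),
            class = "sedbench_simulation")
}

# The generating truth, computed from the model (never re-estimated from
# the emitted sample).
simulation_truth <- function(cfg, n_mc = 20000L) {
  pool <- cfg$taxon_pool
  tr <- cfg$sf_quantile_truth

  # per-class reference FSBI_ref: 25th percentile of the model's reference
  # FSBI distribution, by Monte Carlo on a dedicated substream
  fsbi_ref <- stats::setNames(rep(NA_real_, 3), site_classes())
  set.seed(substream_seed(cfg$seed, 101))
  for (cl in site_classes()) {
    ord <- sample(1:4, n_mc, replace = TRUE, prob = cfg$order_proportions)
    bw <- sim_bw_values(ord, cfg)
    q75 <- tr$intercept[match(ord, tr$order)] +
      tr$slope[match(ord, tr$order)] * bw
    sf <- sim_sf_values(q75, 0, cfg$sf_noise_scale, stats::rnorm(n_mc))
    fs <- draw_fsbi(sf, cfg$class_occ_shift[[cl]], pool)
    fsbi_ref[[cl]] <- quantile7(fs, 0.25)
  }

  # per class x order SF at 50%/75% exceedance probability (exact DP);
  # the occupancy mechanism does not vary with order, so values repeat
  # across orders within a class
  sr <- expand.grid(site_class = site_classes(), order = 1:4,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sr$sr50 <- NA_real_; sr$sr75 <- NA_real_
  for (cl in site_classes()) {
    thr <- fsbi_ref[[cl]]
    s50 <- invert_fsbi_worse(0.50, cfg$class_occ_shift[[cl]], pool, thr)
    s75 <- invert_fsbi_worse(0.75, cfg$class_occ_shift[[cl]], pool, thr)
    sr$sr50[sr$site_class == cl] <- s50
    sr$sr75[sr$site_class == cl] <- s75
  }

  list(sf_quantile = tr, fsbi_ref = fsbi_ref, sr = sr,
       note = paste("sf_quantile lines are exact generator parameters;",
                    "fsbi_ref from the generating model by MC (n = 20000",
                    "per class); sr by exact score convolution"))
}

#' Simulate Wolman pebble counts consistent with event SF values
#'
#' For each event, draws three transects of multinomial particle counts
#' over the 11 size classes. The fines-class probability equals the
#' event's SF/100, so the recomputed SF from the counts is unbiased for
#' the event's SF; the coarse fraction is spread over the gravel-cobble
#' classes with a fixed unimodal shape.
#'
#' @param events Data frame with `event_id` and `sf`.
#' @param particles_per_transect Particles counted per transect (>= 1,
#'   default 50, the minimum a field crew tallies).
#' @param classes Size-class table.
#' @param seed Seed for the draw (defaults derived from nothing; pass one
#'   for reproducibility).
#' @return Data frame `event_id`, `transect_id`, `size_class`, `count` in
#'   long format (3 transects per event).
#' @export
simulate_pebble_counts <- function(events, particles_per_transect = 50,
                                   classes = wolman_size_classes(),
                                   seed = 1L) {
  classes <- validate_size_classes(classes)
  stopifnot(particles_per_transect >= 1,
            all(c("event_id", "sf") %in% names(events)))
  set.seed(substream_seed(seed, 5))
  k <- nrow(classes)
  coarse_shape <- stats::dnorm(seq_len(k - 1), mean = (k - 1) / 2 + 1, sd = 2)
  coarse_shape <- coarse_shape / sum(coarse_shape)
  out <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    pf <- events$sf[i] / 100
    probs <- c(pf, (1 - pf) * coarse_shape)
    cnt <- stats::rmultinom(3, particles_per_transect, probs)
    out[[i]] <- data.frame(
      event_id = rep(as.character(events$event_id[i]), 3 * k),
      transect_id = rep(paste0("T", 1:3), each = k),
      size_class = rep(classes$size_class, 3),
      count = as.integer(cnt), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Probability-survey weights
#'
#' Attaches design weights to events. Under the `"equal"` scheme every
#' weight is 1. Under `"order_stratified"` the weight of an event in
#' stratum (order) h is `extent_h / n_h` — stratum stream extent divided by
#' the stratum sample size, i.e. the inverse inclusion probability of an
#' equal-probability draw within the stratum.
#'
#' @param events Data frame with an `order` column.
#' @param scheme `"equal"` or `"order_stratified"`.
#' @param order_extent Stream extent (any consistent unit) per order 1-4.
#' @return Numeric weight vector aligned with `events`.
#' @export
simulate_weights <- function(events, scheme = c("equal", "order_stratified"),
                             order_extent = c(0.45, 0.30, 0.17, 0.08)) {
  scheme <- match.arg(scheme)
  if (!is.data.frame(events) || nrow(events) == 0)
    stop_sedbench("no events: empty stratum")
  if (scheme == "equal") return(rep(1, nrow(events)))
  stopifnot("order" %in% names(events), length(order_extent) == 4,
            all(order_extent > 0))
  n_h <- tabulate(events$order, nbins = 4)
  present <- sort(unique(events$order))
  if (any(n_h[present] == 0)) stop_sedbench("empty stratum")
  w <- order_extent[events$order] / n_h[events$order]
  as.numeric(w)
}

#' @export
print.sedbench_simulation <- function(x, ...) {
  cat("Synthetic monitoring dataset:", nrow(x$events), "events,",
      nrow(x$occurrences), "taxon occurrences\n")
  cat("  disturbance mix:",
      paste(names(table(x$events$disturbance)),
            as.integer(table(x$events$disturbance)), collapse = ", "), "\n")
  cat("  truth: generating quantile lines, per-class FSBI_ref,",
      "per-cell SR50/SR75\n")
  invisible(x)
}
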