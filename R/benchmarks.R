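# Benchmark-set derivation: per-order SF quantile models, per-class FSBI
# reference percentiles, and per class x order stressor-response benchmarks,
# bundled with provenance metadata.

#' Derive stressor-response benchmarks for every site class x order cell
#'
#' Fits a separate logistic model of "FSBI worse than reference" against SF
#' in each of the 12 site class x stream order cells, attaches fit
#' diagnostics, and inverts each converged model to SR50 and SR75. Cell
#' failures (too few events, single-label data, separation, non-positive
#' slope) are recorded, never fatal for the batch. Models whose
#' Hosmer-Lemeshow p-value signals miscalibration are retained with a
#' warning when the model chi-square and odds-ratio interval still indicate
#' a real SF effect.
#'
#' @param events Data frame with columns `site_class`, `order`, `sf`,
#'   `fsbi`.
#' @param fsbi_ref Named numeric vector of FSBI_ref benchmarks by site
#'   class.
#' @param probabilities Probabilities to invert, default `c(0.5, 0.75)`.
#' @param min_n Minimum events per cell (default 10).
#' @param hl_groups Hosmer-Lemeshow group count.
#' @return List with `table` (one row per cell: n, SR values, coefficients,
#'   diagnostics, availability) and `models` (named list of `sr_logistic`).
#' @export
derive_sr_benchmarks <- function(events, fsbi_ref,
                                 probabilities = c(0.5, 0.75),
                                 min_n = 10, hl_groups = 10) {
  stopifnot(all(c("site_class", "order", "sf", "fsbi") %in% names(events)))
  classes <- site_classes()
  rows <- list()
  models <- list()
  for (cl in classes) {
    for (od in 1:4) {
      key <- paste(cl, od, sep = ".")
      sel <- events$site_class == cl & events$order == od &
        is.finite(events$sf) & is.finite(events$fsbi)
      dat <- events[which(sel), , drop = FALSE]
      row <- list(site_class = cl, order = od, n = nrow(dat),
                  n_worse = NA_integer_, sr50 = NA_real_, sr75 = NA_real_,
                  sr50_exact = NA_real_, sr75_exact = NA_real_,
                  beta0 = NA_real_, se0 = NA_real_, beta1 = NA_real_,
                  se1 = NA_real_, chi_square = NA_real_,
                  chi_square_p = NA_real_, odds_ratio = NA_real_,
                  or_low = NA_real_, or_high = NA_real_,
                  hl_statistic = NA_real_, hl_p = NA_real_,
                  hl_groups = NA_integer_,
                  available = FALSE, note = "")
      res <- tryCatch({
        ref <- fsbi_ref[[cl]]
        if (is.null(ref) || !is.finite(ref))
          stop_sedbench("no FSBI_ref for class ", cl)
        yy <- make_response(dat$fsbi, ref)
        m <- fit_logistic(dat$sf, yy, site_class = cl, order = od,
                          min_n = min_n)
        dg <- logistic_diagnostics(m, dat$sf, yy, hl_groups = hl_groups)
        b <- lapply(probabilities, function(p) invert_logistic(m, p))
        list(m = m, dg = dg, b = b, y = yy)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$note <- conditionMessage(res)
        warn_sedbench("cell ", key, " unavailable: ", row$note)
      } else {
        m <- res$m; dg <- res$dg
        row$n_worse <- sum(res$y)
        row$beta0 <- m$beta0; row$se0 <- m$se0
        row$beta1 <- m$beta1; row$se1 <- m$se1
        row$chi_square <- dg$model_chi_square
        row$chi_square_p <- dg$chi_square_p
        row$odds_ratio <- dg$odds_ratio
        row$or_low <- dg$or_ci[["low"]]; row$or_high <- dg$or_ci[["high"]]
        row$hl_statistic <- dg$hl_statistic
        row$hl_p <- dg$hl_p; row$hl_groups <- dg$hl_groups
        for (k in seq_along(probabilities)) {
          p <- probabilities[k]
          if (isTRUE(all.equal(p, 0.5))) {
            row$sr50_exact <- res$b[[k]]$sf_value
            row$sr50 <- res$b[[k]]$rounded_sf
          } else if (isTRUE(all.equal(p, 0.75))) {
            row$sr75_exact <- res$b[[k]]$sf_value
            row$sr75 <- res$b[[k]]$rounded_sf
          }
        }
        row$available <- TRUE
        if (is.finite(dg$hl_p) && dg$hl_p < 0.05 &&
            dg$chi_square_p < 0.05 && dg$or_ci[["low"]] > 1) {
          row$note <- "HL p < 0.05; retained (chi-square and odds ratio indicate fit)"
          warn_sedbench("cell ", key, ": ", row$note)
        }
        models[[key]] <- m
      }
      rows[[key]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, models = models)
}

#' Derive the full benchmark set from a monitoring dataset
#'
#' The orchestration step: optional one-event-per-stream-segment
#' subsampling of reference and stress events (seeded, when a `comid`
#' column is present), then per-order tau = 0.75 quantile regressions of SF
#' on bankfull width over reference events, per-class 25th-percentile FSBI
#' reference benchmarks over reference events, and per-cell
#' stressor-response benchmarks over the whole dataset. Cells below the
#' minimum sample size are marked unavailable with a warning.
#'
#' @param events Data frame with columns `event_id`, `site_class`, `order`,
#'   `bankfull_width_m`, `sf`, `fsbi`, `disturbance`
#'   (`reference`/`stress`/`ambient`), and optionally `comid`.
#' @param tau Quantile level for the SF reference regression (0.75).
#' @param fsbi_probs Percentile for FSBI_ref as a fraction (0.25).
#' @param min_n_quantile,min_n_fsbi,min_n_logistic Minimum sample sizes.
#' @param subsample_seed Seed for the per-comid subsampling draw; required
#'   whenever `events` has a `comid` column (the draw is otherwise
#'   irreproducible).
#' @param hl_groups Hosmer-Lemeshow group count for diagnostics.
#' @return An object of class `benchmark_set`: `quantile_models` (by
#'   order), `fsbi_ref` (by class, with `fsbi_ref_n`), `sr` (the cell
#'   table), `sr_models`, and `meta` (tau, percentile method, seeds,
#'   dataset fingerprint).
#' @export
derive_benchmark_set <- function(events, tau = 0.75, fsbi_probs = 0.25,
                                 min_n_quantile = 10, min_n_fsbi = 10,
                                 min_n_logistic = 10,
                                 subsample_seed = NULL, hl_groups = 10) {
  req <- c("event_id", "site_class", "order", "bankfull_width_m",
           "sf", "fsbi", "disturbance")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop_sedbench("events missing column(s): ", paste(miss, collapse = ", "))
  events$site_class <- normalize_site_class(events$site_class)

  subsampled <- FALSE
  if ("comid" %in% names(events) && any(!is.na(events$comid))) {
    if (is.null(subsample_seed))
      stop_sedbench("subsample_seed is required when events carry comid ",
                    "identifiers (one reference/stress event per segment ",
                    "is selected at random)")
    events <- subsample_one_per_comid(events, subsample_seed)
    subsampled <- TRUE
  }

  ref <- events[which(events$disturbance == "reference"), , drop = FALSE]

  qmods <- list()
  for (od in 1:4) {
    sel <- ref[which(ref$order == od & is.finite(ref$sf) &
                       is.finite(ref$bankfull_width_m)), , drop = FALSE]
    qmods[[as.character(od)]] <- tryCatch(
      fit_sf_quantile(sel$bankfull_width_m, sel$sf, tau = tau, order = od,
                      min_n = min_n_quantile),
      error = function(e) {
        warn_sedbench("order ", od, " SF quantile model unavailable: ",
                      conditionMessage(e))
        NULL
      })
  }

  fsbi_ref <- stats::setNames(rep(NA_real_, 3), site_classes())
  fsbi_n <- stats::setNames(rep(0L, 3), site_classes())
  for (cl in site_classes()) {
    v <- ref$fsbi[which(ref$site_class == cl & is.finite(ref$fsbi))]
    fsbi_n[[cl]] <- length(v)
    fsbi_ref[[cl]] <- tryCatch(
      compute_fsbi_ref(v, probs = fsbi_probs, min_n = min_n_fsbi),
      error = function(e) {
        warn_sedbench("FSBI_ref unavailable for class ", cl, ": ",
                      conditionMessage(e))
        NA_real_
      })
  }

  sr <- derive_sr_benchmarks(events, fsbi_ref, min_n = min_n_logistic,
                             hl_groups = hl_groups)

  structure(list(
    quantile_models = qmods,
    fsbi_ref = fsbi_ref,
    fsbi_ref_n = fsbi_n,
    sr = sr$table,
    sr_models = sr$models,
    meta = list(tau = tau, fsbi_percentile = fsbi_probs,
                percentile_method = "type7",
                min_n = c(quantile = min_n_quantile, fsbi = min_n_fsbi,
                          logistic = min_n_logistic),
                subsampled = subsampled,
                subsample_seed = subsample_seed,
                dataset_hash = dataset_fingerprint(events),
                n_events = nrow(events),
                created = format(Sys.time(), tz = "UTC"))),
    class = "benchmark_set")
}

# One randomly selected reference/stress event per stream segment (comid);
# ambient events and events without a comid pass through untouched.
subsample_one_per_comid <- function(events, seed) {
  pick <- events$disturbance %in% c("reference", "stress") &
    !is.na(events$comid)
  keep <- rep(TRUE, nrow(events))
  if (any(pick)) {
    idx <- which(pick)
    rng <- local({
      set.seed(substream_seed(seed, 901))
      split_idx <- split(idx, as.character(events$comid[idx]))
      vapply(split_idx, function(v) if (length(v) == 1) v
             else v[sample.int(length(v), 1)], integer(1))
    })
    keep[setdiff(idx, rng)] <- FALSE
  }
  events[keep, , drop = FALSE]
}

#' @export
print.benchmark_set <- function(x, ...) {
  cat("Benchmark set (tau =", x$meta$tau, ", FSBI percentile =",
      x$meta$fsbi_percentile, ")\n")
  cat("SF reference quantile models:\n")
  for (od in names(x$quantile_models)) {
    m <- x$quantile_models[[od]]
    if (is.null(m)) cat("  order", od, ": unavailable\n")
    else cat(sprintf("  order %s: SF_ref = %.5f * BW + %.5f (n = %d)\n",
                     od, m$slope, m$intercept, m$n))
  }
  cat("FSBI_ref by site class:\n")
  for (cl in names(x$fsbi_ref))
    cat(sprintf("  %-10s %s (n = %d)\n", cl,
                ifelse(is.na(x$fsbi_ref[[cl]]), "unavailable",
                       format(x$fsbi_ref[[cl]])), x$fsbi_ref_n[[cl]]))
  cat("Stressor-response cells available:",
      sum(x$sr$available), "of", nrow(x$sr), "\n")
  invisible(x)
}

#' Serialize a benchmark set to JSON
#'
#' Writes the full benchmark set (quantile coefficients, FSBI_ref values,
#' the stressor-response cell table and provenance metadata) as JSON. The
#' creation timestamp is excluded by default so that re-deriving from the
#' same data and seed yields a byte-identical artifact.
#'
#' @param bset A `benchmark_set`.
#' @param path Output file path.
#' @param timestamp Include the creation time (default `FALSE`).
#' @export
write_benchmark_set <- function(bset, path, timestamp = FALSE) {
  stopifnot(inherits(bset, "benchmark_set"))
  qm <- lapply(bset$quantile_models, function(m) {
    if (is.null(m)) NULL
    else m[c("order", "tau", "intercept", "slope", "n", "loss", "method")]
  })
  meta <- bset$meta
  if (!timestamp) meta$created <- NULL
  obj <- list(quantile_models = qm,
              fsbi_ref = as.list(bset$fsbi_ref),
              fsbi_ref_n = as.list(bset$fsbi_ref_n),
              sr = bset$sr,
              meta = meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a benchmark set written by [write_benchmark_set()]
#'
#' Fitted model objects for the stressor-response cells are reconstructed
#' from the stored coefficients (method `"supplied"`).
#'
#' @param path JSON file path.
#' @return A `benchmark_set`.
#' @export
read_benchmark_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  qm <- list()
  for (od in as.character(1:4)) {
    m <- obj$quantile_models[[od]]
    qm[[od]] <- if (is.null(m) || is.null(m$intercept)) NULL else
      structure(list(order = as.integer(m$order), tau = m$tau,
                     intercept = m$intercept, slope = m$slope,
                     n = as.integer(m$n), loss = m$loss %||% NA_real_,
                     method = m$method %||% "supplied"),
                class = "sf_quantile_model")
  }
  sr <- as.data.frame(obj$sr, stringsAsFactors = FALSE)
  models <- list()
  for (i in seq_len(nrow(sr))) {
    if (!isTRUE(sr$available[i])) next
    key <- paste(sr$site_class[i], sr$order[i], sep = ".")
    models[[key]] <- logistic_model(sr$beta0[i], sr$beta1[i],
                                    se0 = sr$se0[i], se1 = sr$se1[i],
                                    site_class = sr$site_class[i],
                                    order = sr$order[i], n = sr$n[i])
  }
  structure(list(quantile_models = qm,
                 fsbi_ref = unlist(obj$fsbi_ref),
                 fsbi_ref_n = unlist(obj$fsbi_ref_n),
                 sr = sr, sr_models = models,
                 meta = obj$meta),
            class = "benchmark_set")
}

#' Export SF reference model coefficients as a table
#'
#' One row per stream order with the fitted quantile-regression equation —
#' the coefficient table a monitoring program would publish.
#'
#' @param bset A `benchmark_set`.
#' @return Data frame with columns `order`, `intercept`, `slope`, `n`,
#'   `equation`.
#' @export
export_sf_ref_table <- function(bset) {
  stopifnot(inherits(bset, "benchmark_set"))
  rows <- lapply(names(bset$quantile_models), function(od) {
    m <- bset$quantile_models[[od]]
    if (is.null(m))
      return(data.frame(order = as.integer(od), intercept = NA_real_,
                        slope = NA_real_, n = NA_integer_,
                        equation = "unavailable"))
    data.frame(order = as.integer(od), intercept = m$intercept,
               slope = m$slope, n = m$n,
               equation = sprintf("SF_ref = %.5f * BW + %.5f",
                                  m$slope, m$intercept))
  })
  do.call(rbind, rows)
}

#' Export the stressor-response benchmark table
#'
#' One row per site class x order cell with sample size, SR50/SR75,
#' coefficients with standard errors, model chi-square, odds-ratio interval
#' and Hosmer-Lemeshow p-value.
#'
#' @param bset A `benchmark_set`.
#' @return Data frame ready for `write.csv()`.
#' @export
export_sr_table <- function(bset) {
  stopifnot(inherits(bset, "benchmark_set"))
  t <- bset$sr
  data.frame(site_class = t$site_class, order = t$order, n = t$n,
             sr50 = t$sr50, sr75 = t$sr75,
             intercept_se = ifelse(t$available,
                                   sprintf("%.3g (%.2g)", t$beta0, t$se0), ""),
             slope_se = ifelse(t$available,
                               sprintf("%.3g (%.2g)", t$beta1, t$se1), ""),
             model_chi_square = t$chi_square,
             odds_ratio_ci = ifelse(t$available,
                                    sprintf("[%.4f-%.4f]", t$or_low, t$or_high),
                                    ""),
             hl_p = t$hl_p, available = t$available, note = t$note,
             stringsAsFactors = FALSE)
}
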