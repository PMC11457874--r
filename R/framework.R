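# Evidence framework: joint SF and FSBI reference-benchmark status rates
# the strength of evidence for a sediment-induced community change.

#' Rate the strength of evidence from benchmark status
#'
#' A pure function of the two achievement flags: both achieved ->
#' `"unlikely"`, exactly one achieved -> `"mixed_evidence"`, neither
#' achieved -> `"likely"`. The magnitude of any exceedance plays no role.
#'
#' @param sf_achieved Logical: SF at or below the reach SF_ref benchmark.
#' @param fsbi_achieved Logical: FSBI at or above the class FSBI_ref.
#' @return Factor with levels `unlikely`, `mixed_evidence`, `likely`.
#' @export
#' @examples
#' classify_event(TRUE, TRUE)    # unlikely
#' classify_event(FALSE, TRUE)   # mixed_evidence
#' classify_event(FALSE, FALSE)  # likely
classify_event <- function(sf_achieved, fsbi_achieved) {
  if (any(is.na(sf_achieved)) || any(is.na(fsbi_achieved)))
    stop_sedbench("achievement flags must be TRUE/FALSE, not NA")
  n_achieved <- as.integer(sf_achieved) + as.integer(fsbi_achieved)
  factor(c("likely", "mixed_evidence", "unlikely")[n_achieved + 1L],
         levels = c("unlikely", "mixed_evidence", "likely"))
}

#' Assess every sample event in a dataset
#'
#' Computes each event's reach-specific SF_ref (from its order's quantile
#' model and bankfull width) and class FSBI_ref, rates both benchmarks as
#' achieved (at-or-better, with equality counting as achievement) or not,
#' and classifies the strength of evidence. Events missing either
#' indicator, a usable model cell, or required covariates receive no rating
#' and are tallied in an exclusion report — the framework is defined on
#' paired data only.
#'
#' @param events Data frame with `event_id`, `site_class`, `order`,
#'   `bankfull_width_m`, `sf`, `fsbi`.
#' @param bset A `benchmark_set`.
#' @return List of class `framework_assessment`: `ratings` (per-event
#'   table with benchmarks used), `summary` (counts and shares per
#'   rating), and `excluded` (counts by reason).
#' @export
assess_dataset <- function(events, bset) {
  stopifnot(inherits(bset, "benchmark_set"))
  req <- c("event_id", "site_class", "order", "bankfull_width_m", "sf",
           "fsbi")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop_sedbench("events missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(events)) stop_sedbench("no events to assess")
  ev <- events
  ev$site_class <- normalize_site_class(ev$site_class)

  n <- nrow(ev)
  sf_ref <- rep(NA_real_, n)
  for (od in 1:4) {
    m <- bset$quantile_models[[as.character(od)]]
    sel <- which(ev$order == od & is.finite(ev$bankfull_width_m) &
                   ev$bankfull_width_m > 0)
    if (!is.null(m) && length(sel))
      sf_ref[sel] <- predict_sf_ref(m, ev$bankfull_width_m[sel])
  }
  fsbi_ref <- unname(bset$fsbi_ref[ev$site_class])

  reason <- rep(NA_character_, n)
  reason[!is.finite(ev$sf)] <- "missing SF"
  reason[is.na(reason) & !is.finite(ev$fsbi)] <- "missing FSBI"
  reason[is.na(reason) & (is.na(ev$site_class) | !is.finite(fsbi_ref))] <-
    "no FSBI_ref for site class"
  reason[is.na(reason) & !is.finite(sf_ref)] <-
    "no SF_ref (order model or bankfull width unavailable)"
  ok <- is.na(reason)

  sf_ach <- ev$sf[ok] <= sf_ref[ok]
  fsbi_ach <- ev$fsbi[ok] >= fsbi_ref[ok]
  ratings <- data.frame(
    event_id = as.character(ev$event_id[ok]),
    site_class = ev$site_class[ok], order = ev$order[ok],
    sf = ev$sf[ok], sf_ref = sf_ref[ok], sf_achieved = sf_ach,
    fsbi = ev$fsbi[ok], fsbi_ref = fsbi_ref[ok], fsbi_achieved = fsbi_ach,
    rating = classify_event(sf_ach, fsbi_ach),
    stringsAsFactors = FALSE)

  counts <- table(factor(ratings$rating,
                         levels = c("unlikely", "mixed_evidence", "likely")))
  summary <- data.frame(rating = names(counts),
                        n = as.integer(counts),
                        share = if (nrow(ratings))
                          as.numeric(counts) / nrow(ratings) else NA_real_,
                        stringsAsFactors = FALSE)
  excl <- table(reason[!ok])
  structure(list(ratings = ratings, summary = summary,
                 excluded = data.frame(reason = names(excl),
                                       n = as.integer(excl),
                                       stringsAsFactors = FALSE),
                 n_events = n),
            class = "framework_assessment")
}

#' @export
print.framework_assessment <- function(x, ...) {
  cat("Framework assessment:", nrow(x$ratings), "rated of", x$n_events,
      "events\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-15s %5d  (%.1f%%)\n", x$summary$rating[i],
                x$summary$n[i], 100 * x$summary$share[i]))
  if (nrow(x$excluded)) {
    cat("Excluded:\n")
    for (i in seq_len(nrow(x$excluded)))
      cat(sprintf("  %-50s %d\n", x$excluded$reason[i], x$excluded$n[i]))
  }
  invisible(x)
}
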