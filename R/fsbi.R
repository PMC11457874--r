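# Fine Sediment Biotic Index: occurrence-only sum of per-taxon sediment
# sensitivity scores. Higher FSBI = more sediment-sensitive taxa present.

normalize_taxon <- function(x) {
  x <- trimws(tolower(as.character(x)))
  gsub("\\s+", " ", x)
}

#' Validate a taxon sensitivity score table
#'
#' @param scores Data frame with columns `taxon` and `score`, or a named
#'   numeric vector. Scores must be non-negative; taxon names must be unique
#'   after case/whitespace normalization.
#' @return A data frame with columns `taxon` (normalized), `taxon_original`
#'   and `score`.
#' @export
as_score_table <- function(scores) {
  if (is.numeric(scores) && !is.null(names(scores)))
    scores <- data.frame(taxon = names(scores), score = as.numeric(scores))
  if (!is.data.frame(scores) || !all(c("taxon", "score") %in% names(scores)))
    stop_sedbench("score table needs columns taxon and score")
  if (nrow(scores) == 0) stop_sedbench("score table is empty")
  sc <- as.numeric(scores$score)
  if (any(!is.finite(sc)) || any(sc < 0))
    stop_sedbench("sensitivity scores must be finite and >= 0")
  norm <- normalize_taxon(scores$taxon)
  if (any(duplicated(norm)))
    stop_sedbench("duplicate taxon name(s) after normalization: ",
                  paste(unique(norm[duplicated(norm)]), collapse = ", "))
  data.frame(taxon = norm, taxon_original = as.character(scores$taxon),
             score = sc, stringsAsFactors = FALSE)
}

#' FSBI score for a single sample
#'
#' Sums sensitivity scores over the distinct taxa present. Duplicated taxon
#' records collapse (the index uses occurrence only, never abundance).
#'
#' @param taxa Character vector of taxa present in the sample.
#' @param scores Score table, see [as_score_table()].
#' @param on_missing What to do with present taxa absent from the score
#'   table: `"ignore"` (default; they contribute nothing), `"warn"`, or
#'   `"error"`.
#' @return A single numeric FSBI value (>= 0).
#' @export
#' @examples
#' tab <- data.frame(taxon = c("A", "B", "C"), score = c(10, 5, 0))
#' score_sample(c("A", "A", "B"), tab)  # 15
score_sample <- function(taxa, scores,
                         on_missing = c("ignore", "error", "warn")) {
  on_missing <- match.arg(on_missing)
  tab <- as_score_table(scores)
  present <- unique(normalize_taxon(taxa))
  present <- present[!is.na(present) & nzchar(present)]
  if (!length(present)) return(0)
  unknown <- setdiff(present, tab$taxon)
  if (length(unknown)) {
    msg <- paste0("taxa not in score table: ", paste(unknown, collapse = ", "))
    if (on_missing == "error") stop_sedbench(msg)
    if (on_missing == "warn") warn_sedbench(msg)
  }
  sum(tab$score[match(intersect(present, tab$taxon), tab$taxon)])
}

#' FSBI scores for a table of taxa occurrences
#'
#' @param occurrences Data frame with columns `event_id` and `taxon`.
#' @inheritParams score_sample
#' @return Data frame with columns `event_id`, `fsbi` and `n_taxa`
#'   (distinct taxa recorded, whether or not scored).
#' @export
score_events <- function(occurrences, scores,
                         on_missing = c("ignore", "error", "warn")) {
  on_missing <- match.arg(on_missing)
  if (!is.data.frame(occurrences) ||
      !all(c("event_id", "taxon") %in% names(occurrences)))
    stop_sedbench("occurrences need columns event_id and taxon")
  ids <- unique(as.character(occurrences$event_id))
  fs <- vapply(ids, function(id) {
    score_sample(occurrences$taxon[occurrences$event_id == id], scores,
                 on_missing = on_missing)
  }, numeric(1))
  nt <- vapply(ids, function(id) {
    length(unique(normalize_taxon(
      occurrences$taxon[occurrences$event_id == id])))
  }, integer(1))
  data.frame(event_id = ids, fsbi = unname(fs), n_taxa = unname(nt),
             stringsAsFactors = FALSE)
}

#' Derive per-taxon sediment tolerance values from paired data
#'
#' For each taxon, the 75th percentile (type 7) of SF values at the events
#' where it occurs — the tolerance statistic underlying FSBI score
#' assignment. Mapping the percentile to a score is left to a user-supplied
#' binning table, which this package does not prescribe.
#'
#' @param events Data frame with columns `event_id` and `sf`.
#' @param occurrences Data frame with columns `event_id` and `taxon`.
#' @param min_events Minimum number of occurrence events for a taxon to be
#'   reported (default 5); taxa below it are dropped with a warning.
#' @return Data frame with columns `taxon`, `n_events` and `sf_p75`.
#' @export
derive_taxon_tolerance <- function(events, occurrences, min_events = 5) {
  stopifnot(all(c("event_id", "sf") %in% names(events)),
            all(c("event_id", "taxon") %in% names(occurrences)))
  sf <- events$sf[match(as.character(occurrences$event_id),
                        as.character(events$event_id))]
  taxon <- normalize_taxon(occurrences$taxon)
  keep <- !is.na(sf)
  # one record per taxon x event (occurrence-only)
  key <- !duplicated(paste(taxon, occurrences$event_id)) & keep
  taxon <- taxon[key]; sf <- sf[key]
  tab <- split(sf, taxon)
  n <- vapply(tab, length, integer(1))
  low <- names(tab)[n < min_events]
  if (length(low))
    warn_sedbench("taxa below the minimum of ", min_events,
                  " occurrence events were omitted: ",
                  paste(low, collapse = ", "))
  tab <- tab[n >= min_events]
  if (!length(tab))
    return(data.frame(taxon = character(), n_events = integer(),
                      sf_p75 = numeric()))
  data.frame(taxon = names(tab),
             n_events = vapply(tab, length, integer(1)),
             sf_p75 = vapply(tab, function(v) quantile7(v, 0.75), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Demonstration FSBI score table
#'
#' A 40-taxon demonstration sensitivity-score table shipped with the
#' package. Taxon names are common Northwest US stream macroinvertebrate
#' genera, but the scores are synthetic values constructed for examples and
#' tests — they are *not* the published 206-taxon FSBI score table, which
#' must be supplied as a user CSV for production scoring.
#'
#' @return Data frame with columns `taxon` and `score`.
#' @export
fsbi_demo_scores <- function() {
  pool <- default_taxon_pool()
  data.frame(taxon = pool$taxon, score = pool$score, stringsAsFactors = FALSE)
}
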