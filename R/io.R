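# CSV interchange: sample-event, pebble-count, taxa and score tables, with
# per-row validation reports.

#' Read and validate a sample-event table
#'
#' Required columns: `event_id`, `site_class`, `order`,
#' `bankfull_width_m`. Optional: `sf`, `fsbi`, `smi2`, `oe`, `weight`,
#' `disturbance`, `comid`. Site-class names are normalized to
#' `mountains`/`foothills`/`ppbv`; order must be an integer 1-4 (the
#' benchmarks cover wadable streams only) and bankfull width must be
#' positive. Every invalid row is reported with its row number in a single
#' error.
#'
#' @param path CSV file path.
#' @return Validated data frame of sample events.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("event_id", "site_class", "order", "bankfull_width_m")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_sedbench("events file missing column(s): ",
                  paste(miss, collapse = ", "))
  problems <- character()
  cls <- normalize_site_class(df$site_class)
  bad <- which(is.na(cls))
  if (length(bad))
    problems <- c(problems, sprintf(
      "row %d: unknown site class '%s' (expected mountains/foothills/ppbv)",
      bad, df$site_class[bad]))
  ordn <- suppressWarnings(as.numeric(df$order))
  bad <- which(!check_orders(ordn))
  if (length(bad))
    problems <- c(problems, sprintf(
      "row %d: order must be an integer 1-4 (got '%s')", bad, df$order[bad]))
  bwn <- suppressWarnings(as.numeric(df$bankfull_width_m))
  bad <- which(is.na(bwn) | bwn <= 0)
  if (length(bad))
    problems <- c(problems, sprintf(
      "row %d: bankfull_width_m must be positive (got '%s')",
      bad, df$bankfull_width_m[bad]))
  if ("weight" %in% names(df)) {
    wn <- suppressWarnings(as.numeric(df$weight))
    bad <- which(!is.na(df$weight) & (is.na(wn) | wn <= 0))
    if (length(bad))
      problems <- c(problems, sprintf(
        "row %d: weight must be positive (got '%s')", bad, df$weight[bad]))
  }
  if (length(problems))
    stop_sedbench("invalid event rows:\n  ",
                  paste(problems, collapse = "\n  "))
  df$site_class <- cls
  df$order <- as.integer(ordn)
  df$bankfull_width_m <- bwn
  for (col in c("sf", "fsbi", "smi2", "oe", "weight"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  if (!"weight" %in% names(df)) df$weight <- 1
  df$event_id <- as.character(df$event_id)
  if (anyDuplicated(df$event_id))
    stop_sedbench("duplicate event_id values: ",
                  paste(unique(df$event_id[duplicated(df$event_id)]),
                        collapse = ", "))
  df
}

#' Read a pebble-count table
#'
#' Columns: `event_id`, `transect_id`, `size_class`, `count`. Labels must
#' match the size-class table in use.
#'
#' @param path CSV file path.
#' @param classes Size-class table for label validation.
#' @return Validated data frame.
#' @export
read_pebble_counts <- function(path, classes = wolman_size_classes()) {
  classes <- validate_size_classes(classes)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("event_id", "transect_id", "size_class", "count")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_sedbench("pebble file missing column(s): ",
                  paste(miss, collapse = ", "))
  unknown <- setdiff(unique(df$size_class), classes$size_class)
  if (length(unknown))
    stop_sedbench("unknown size class label(s): ",
                  paste(unknown, collapse = ", "))
  bad <- which(is.na(df$count) | df$count < 0 | df$count != round(df$count))
  if (length(bad))
    stop_sedbench("invalid counts at row(s): ", paste(bad, collapse = ", "))
  df$count <- as.integer(df$count)
  df
}

#' Read a taxa-occurrence table
#'
#' Columns: `event_id`, `taxon`. Duplicate records collapse downstream
#' (the FSBI is occurrence-only).
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_taxa <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("event_id", "taxon"), names(df))
  if (length(miss))
    stop_sedbench("taxa file missing column(s): ",
                  paste(miss, collapse = ", "))
  df$event_id <- as.character(df$event_id)
  df
}

#' Read a taxon sensitivity score table
#'
#' Columns: `taxon`, `score`. Validated by [as_score_table()].
#'
#' @param path CSV file path.
#' @return Normalized score table.
#' @export
read_score_table <- function(path) {
  as_score_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
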