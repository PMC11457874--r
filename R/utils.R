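#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# Round half away from zero (reported benchmarks are printed as integers;
# base round() is banker's rounding and would map 54.5 to 54).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Hyndman-Fan type-7 sample quantile, the convention recorded in benchmark
# metadata and used for every percentile in the package.
quantile7 <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

# Deterministic substream seeds: one global seed fans out to independent
# per-operation seeds so parts of a simulation can be regenerated alone.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  s <- abs(as.numeric(seed)) %% 1e5
  as.integer((s * 40503 + as.numeric(stream) * 30269 + 7) %% 2147483629)
}

# Cheap deterministic fingerprint for provenance metadata. Hashes a compact
# structural summary of a data frame (dims, names, column summaries) rather
# than every byte; collisions are acceptable for provenance, speed matters.
dataset_fingerprint <- function(df) {
  stopifnot(is.data.frame(df))
  summarise_col <- function(v) {
    if (is.numeric(v)) {
      s <- v[is.finite(v)]
      paste(length(v), sum(is.na(v)),
            format(sum(s), digits = 15),
            format(sum(s^2), digits = 15),
            if (length(s)) format(range(s), digits = 15) else "NA",
            collapse = " ")
    } else {
      v <- as.character(v)
      paste(length(v), sum(is.na(v)), length(unique(v)),
            paste(utils::head(sort(unique(v)), 5), collapse = ","))
    }
  }
  txt <- paste(nrow(df), ncol(df),
               paste(names(df), collapse = "|"),
               paste(vapply(df, summarise_col, character(1)), collapse = "|"),
               sep = "||")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

# Shared site-class vocabulary ------------------------------------------------

#' Site classes recognised by the package
#'
#' Three ecoregion-based site classes are used to stratify FSBI reference
#' benchmarks and stressor-response models: `"mountains"`, `"foothills"` and
#' `"ppbv"` (plains, plateaus and broad valleys).
#'
#' @return Character vector of the three canonical class names.
#' @export
site_classes <- function() c("mountains", "foothills", "ppbv")

normalize_site_class <- function(x) {
  raw <- trimws(tolower(as.character(x)))
  raw <- gsub("\\s+", " ", raw)
  out <- rep(NA_character_, length(raw))
  out[raw %in% c("mountains", "mountain", "mtns")] <- "mountains"
  out[raw %in% c("foothills", "foothill")] <- "foothills"
  out[raw %in% c("ppbv", "plains", "plains, plateaus, and broad valleys",
                 "plains plateaus and broad valleys")] <- "ppbv"
  out
}

check_orders <- function(order) {
  ok <- !is.na(order) & order == as.integer(order) & order >= 1 & order <= 4
  ok
}

stop_sedbench <- function(...) stop(..., call. = FALSE)
warn_sedbench <- function(...) warning(..., call. = FALSE)
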