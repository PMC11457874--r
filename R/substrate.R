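#' Percent surface fine sediment from pooled pebble counts
#'
#' Computes SF, the percent of counted surface particles in size classes
#' finer than 2.5 mm, for each sample event. All transects of an event are
#' pooled before division, so SF is invariant to how particles were split
#' across transects.
#'
#' @param pebbles Data frame with columns `event_id`, `transect_id`,
#'   `size_class` and `count` (non-negative integers). Size-class labels
#'   must match `classes$size_class`.
#' @param classes Size-class table, see [wolman_size_classes()].
#' @return Data frame with one row per event: `event_id`, `sf_percent`
#'   (in \[0, 100\]) and `total_particles`.
#' @export
#' @examples
#' pc <- data.frame(event_id = "e1", transect_id = rep(1:3, each = 2),
#'                  size_class = rep(c("<2.5", "45-64"), 3),
#'                  count = c(10, 40, 10, 40, 10, 40))
#' compute_sf(pc)  # 30 fines of 150 -> 20%
compute_sf <- function(pebbles, classes = wolman_size_classes()) {
  classes <- validate_size_classes(classes)
  req <- c("event_id", "size_class", "count")
  if (!is.data.frame(pebbles) || !all(req %in% names(pebbles)))
    stop_sedbench("pebble counts need columns event_id, size_class, count")
  unknown <- setdiff(unique(pebbles$size_class), classes$size_class)
  if (length(unknown))
    stop_sedbench("unknown size class label(s): ",
                  paste(unknown, collapse = ", "))
  cnt <- pebbles$count
  if (!is.numeric(cnt) || any(!is.finite(cnt)) || any(cnt < 0) ||
      any(cnt != round(cnt)))
    stop_sedbench("counts must be non-negative integers")

  fines_classes <- classes$size_class[classes$fines]
  ev <- as.character(pebbles$event_id)
  total <- tapply(cnt, ev, sum)
  fines <- tapply(ifelse(pebbles$size_class %in% fines_classes, cnt, 0), ev, sum)
  if (any(total < 1))
    stop_sedbench("event(s) with zero pooled particles: ",
                  paste(names(total)[total < 1], collapse = ", "))
  out <- data.frame(event_id = names(total),
                    sf_percent = 100 * as.numeric(fines) / as.numeric(total),
                    total_particles = as.integer(total),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(match(out$event_id, unique(ev))), , drop = FALSE]
}
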