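#' Default Wolman pebble-count size classes
#'
#' Eleven ordered particle size classes over the intermediate-axis diameter,
#' on a half-phi modified Wentworth series. Classes are half-open
#' `[lower, upper)` in millimetres; the finest class (`"<2.5"`) is the sand
#' and fines ("SF") fraction and the coarsest class is open-ended so any
#' boulder-sized particle is still binned. The exact boundaries are a
#' package default and can be replaced with a program-specific table.
#'
#' @return A data frame with columns `size_class` (label), `lower` and
#'   `upper` (mm, half-open interval), and logical `fines` marking classes
#'   entirely below the 2.5 mm sand-and-fines cutoff.
#' @seealso [bin_particle()], [compute_sf()]
#' @export
#' @examples
#' wolman_size_classes()
wolman_size_classes <- function() {
  breaks <- c(0, 2.5, 6, 15, 32, 45, 64, 90, 128, 180, 256, Inf)
  lower <- breaks[-length(breaks)]
  upper <- breaks[-1]
  labels <- c("<2.5", "2.5-6", "6-15", "15-32", "32-45", "45-64",
              "64-90", "90-128", "128-180", "180-256", ">=256")
  data.frame(size_class = labels, lower = lower, upper = upper,
             fines = upper <= 2.5, stringsAsFactors = FALSE)
}

validate_size_classes <- function(classes) {
  stopifnot(is.data.frame(classes),
            all(c("size_class", "lower", "upper") %in% names(classes)))
  if (nrow(classes) != 11L)
    stop_sedbench("size-class table must have exactly 11 classes, got ",
                  nrow(classes))
  if (any(duplicated(classes$size_class)))
    stop_sedbench("size-class labels must be unique")
  if (any(diff(classes$lower) <= 0) || any(classes$upper <= classes$lower) ||
      any(utils::head(classes$upper, -1) != classes$lower[-1]))
    stop_sedbench("size-class boundaries must be strictly ascending and contiguous")
  if (is.null(classes$fines)) classes$fines <- classes$upper <= 2.5
  classes
}

#' Assign particle diameters to size classes
#'
#' Bins measured intermediate-axis diameters into the ordered size classes.
#' Intervals are half-open `[lower, upper)`, so a particle measured exactly
#' at 2.5 mm falls in the `"2.5-6"` class and is *not* counted as fines;
#' fines are particles strictly smaller than 2.5 mm.
#'
#' @param diameter_mm Numeric vector of particle diameters (mm), all > 0.
#' @param classes Size-class table as returned by [wolman_size_classes()].
#' @return Character vector of size-class labels, one per particle.
#' @export
#' @examples
#' bin_particle(c(1, 2.5, 300))
bin_particle <- function(diameter_mm, classes = wolman_size_classes()) {
  classes <- validate_size_classes(classes)
  if (!is.numeric(diameter_mm) || any(!is.finite(diameter_mm)) ||
      any(diameter_mm <= 0))
    stop_sedbench("particle diameters must be positive finite numbers")
  breaks <- c(classes$lower, classes$upper[nrow(classes)])
  idx <- findInterval(diameter_mm, breaks)
  idx <- pmin(idx, nrow(classes))  # diameters at/above the top boundary
  classes$size_class[idx]
}
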