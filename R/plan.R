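#' Build a stepped isolation-window acquisition plan
#'
#' One measurement cycle records a fragmentation event at every position of
#' the isolation window centre, starting at `nominal_mass + start_offset`
#' and moving in `step` increments up to `nominal_mass + end_offset`. The
#' default plan (offsets -0.7 / +0.9 Th, 0.02 Th step, 1 Th window) yields
#' 81 fragmentation events per cycle.
#'
#' The event count is `floor((end_offset - start_offset) / step) + 1`, with
#' the final centre never exceeding `nominal_mass + end_offset`; it does not
#' depend on the nominal mass.
#'
#' @param nominal_mass nominal m/z of the targeted isobars (Th).
#' @param start_offset first window centre relative to `nominal_mass` (Th).
#' @param end_offset last window centre relative to `nominal_mass` (Th).
#' @param step centre increment between consecutive events (Th, > 0).
#' @param isolation_width full isolation window width (Th, > 0).
#' @return an object of class `scan_plan`.
#' @export
#' @examples
#' plan <- build_plan(342)
#' plan$n_events          # 81
#' head(plan_centers(plan))
build_plan <- function(nominal_mass, start_offset = -0.7, end_offset = 0.9,
                       step = 0.02, isolation_width = 1) {
  if (!is.numeric(nominal_mass) || length(nominal_mass) != 1L ||
      nominal_mass <= 0)
    stop("nominal_mass must be a single positive number")
  if (step <= 0) stop("step must be > 0")
  if (end_offset <= start_offset)
    stop("end_offset must be greater than start_offset")
  if (isolation_width <= 0) stop("isolation_width must be > 0")
  # guard against 1.6/0.02 landing a hair below 80 in floating point
  n <- floor((end_offset - start_offset) / step + 1e-9) + 1L
  structure(
    list(nominal_mass = nominal_mass, start_offset = start_offset,
         end_offset = end_offset, step = step,
         isolation_width = isolation_width, n_events = as.integer(n)),
    class = "scan_plan")
}

#' Isolation-window centres of a plan
#'
#' @param plan a [build_plan()] object.
#' @return strictly increasing numeric vector of centres (Th), uniformly
#'   spaced by `plan$step` and capped at `nominal_mass + end_offset`.
#' @export
plan_centers <- function(plan) {
  stopifnot(inherits(plan, "scan_plan"))
  cen <- plan$nominal_mass + plan$start_offset +
    (seq_len(plan$n_events) - 1L) * plan$step
  cen[cen <= plan$nominal_mass + plan$end_offset + 1e-9]
}

#' @export
print.scan_plan <- function(x, ...) {
  cat(sprintf(paste0("<scan_plan> %d events: centres %.4f .. %.4f Th ",
                     "(step %.3g, window %.3g Th)\n"),
              x$n_events, x$nominal_mass + x$start_offset,
              x$nominal_mass + x$start_offset + (x$n_events - 1L) * x$step,
              x$step, x$isolation_width))
  invisible(x)
}

#' Plan schedule as a data frame
#'
#' @param x a `scan_plan`.
#' @param ... unused.
#' @return data frame with `scan_index`, `isolation_center`,
#'   `isolation_width`.
#' @export
as.data.frame.scan_plan <- function(x, ...) {
  cen <- plan_centers(x)
  data.frame(scan_index = seq_along(cen) - 1L, isolation_center = cen,
             isolation_width = x$isolation_width)
}
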