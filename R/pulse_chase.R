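# Pulse-chase quantification: per-nucleus fluorescence summaries over chase
# times and the dilution-only decay expectation (50% loss per cell cycle).

#' Dilution-only decay model
#'
#' Expected fraction remaining after `t` hours is `0.5^(t / T)` with `T` the
#' cell-cycle length; one cycle halves the signal. A growth rate (divisions
#' per hour) may be given instead, with `T = ln(2) / growth_rate`.
#'
#' @param initial_signal signal at t = 0 (default 100, i.e. percent).
#' @param cell_cycle_length cell-cycle length in hours.
#' @param growth_rate optional exponential growth rate (per hour) overriding
#'   `cell_cycle_length`.
#' @return a `dilution_model` list.
#' @export
dilution_model <- function(initial_signal = 100, cell_cycle_length = 24,
                           growth_rate = NULL) {
  if (!is.null(growth_rate)) {
    if (growth_rate <= 0) stop("dilution_model: growth rate must be positive")
    cell_cycle_length <- log(2) / growth_rate
  }
  if (cell_cycle_length <= 0) stop("dilution_model: cell-cycle length must be positive")
  structure(list(initial_signal = initial_signal,
                 cell_cycle_length = cell_cycle_length,
                 growth_rate = growth_rate %||% (log(2) / cell_cycle_length)),
            class = "dilution_model")
}

#' Expected signal remaining under dilution-only loss
#' @param model a [dilution_model()].
#' @param times chase times in hours.
#' @return expected signal at each time, on the scale of `initial_signal`.
#' @export
expected_dilution <- function(model, times) {
  stopifnot(inherits(model, "dilution_model"))
  model$initial_signal * 0.5^(times / model$cell_cycle_length)
}

#' Per-chase-time retention summary vs the dilution expectation
#'
#' Mean, SD and n per chase time, the dilution-only expectation at that
#' time, and an excess-loss flag raised when the group mean falls below the
#' expectation by more than `z_crit` standard errors (one-sided z-style
#' comparison against the dashed dilution line).
#'
#' @param intensity_table data.frame with columns `chase_time_h` and
#'   `intensity` (one row per nucleus).
#' @param model a [dilution_model()]; its `initial_signal` is taken from the
#'   earliest chase group when `rescale = TRUE`.
#' @param z_crit one-sided z threshold; default 1.645 (5%).
#' @param rescale anchor the expectation to the mean of the earliest group.
#' @return data.frame (chase_time_h, n, mean, sd, expected, excess_loss).
#' @export
retention_summary <- function(intensity_table, model = dilution_model(),
                              z_crit = 1.645, rescale = TRUE) {
  stopifnot(all(c("chase_time_h", "intensity") %in% names(intensity_table)))
  keep <- !is.na(intensity_table$intensity)
  tab <- intensity_table[keep, , drop = FALSE]
  if (!nrow(tab)) stop("retention_summary: no intensities")
  times <- sort(unique(tab$chase_time_h))
  groups <- lapply(times, function(t) tab$intensity[tab$chase_time_h == t])
  empty <- lengths(groups) == 0L
  if (any(empty)) {
    warning("retention_summary: empty chase groups excluded")
    times <- times[!empty]; groups <- groups[!empty]
  }
  if (rescale) {
    model$initial_signal <- mean(groups[[1L]]) / 0.5^(times[1L] / model$cell_cycle_length)
  }
  exp_v <- expected_dilution(model, times)
  out <- data.frame(
    chase_time_h = times,
    n = lengths(groups),
    mean = vapply(groups, mean, numeric(1L)),
    sd = vapply(groups, stats::sd, numeric(1L)))
  out$expected <- exp_v
  se <- out$sd / sqrt(out$n)
  out$excess_loss <- !is.na(se) & se > 0 & (out$expected - out$mean) / se > z_crit
  out
}
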