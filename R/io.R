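#' Write simulation outputs
#'
#' Serializes a trajectory as `prefix_timeseries.csv` (columns `time`,
#' `V_p`, `K_p`, `I`, `N`, `M`, `mean_size`), `prefix_sizedist.csv`
#' (`lower`, `upper`, `count`) and `prefix_summary.json` (final
#' observables, stop time and the parameter set). Values round-trip
#' through [read_timeseries()] / [read_summary()] at full double
#' precision.
#'
#' @param traj an `"sia_trajectory"`.
#' @param prefix output path prefix.
#' @param breaks size-distribution bin edges (mm^3), see
#'   [size_distribution()].
#' @return Invisibly, the three file paths.
#' @export
write_outputs <- function(traj, prefix,
                          breaks = 10^seq(-6, 4, by = 1)) {
  stopifnot(inherits(traj, "sia_trajectory"))
  ts_path <- paste0(prefix, "_timeseries.csv")
  sd_path <- paste0(prefix, "_sizedist.csv")
  js_path <- paste0(prefix, "_summary.json")

  ts <- data.frame(time = traj$times, V_p = traj$V_p, K_p = traj$K_p,
                   I = traj$I, N = traj$N, M = traj$M,
                   mean_size = traj$mean_size)
  write.csv(format(ts, digits = 17, scientific = TRUE, trim = TRUE),
            ts_path, row.names = FALSE, quote = FALSE)
  write.csv(format(size_distribution(traj, breaks), digits = 17,
                   scientific = TRUE, trim = TRUE),
            sd_path, row.names = FALSE, quote = FALSE)

  n <- length(traj$times)
  summary <- list(
    final_time = traj$times[n], V_p = traj$V_p[n], K_p = traj$K_p[n],
    I = traj$I[n], N = traj$N[n],
    N_visible = count_visible(traj, traj$visible_volume),
    M = traj$M[n], mean_size = traj$mean_size[n],
    visible_volume = traj$visible_volume, dt = traj$dt, sia = traj$sia,
    stop_burden = traj$stop_burden, stop_time = traj$stop_time,
    parameters = unclass(traj$params)
  )
  jsonlite::write_json(summary, js_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(c(timeseries = ts_path, sizedist = sd_path, summary = js_path))
}

#' Read simulation outputs back
#'
#' @param path file written by [write_outputs()].
#' @return `read_timeseries()`: a data.frame; `read_summary()`: a list.
#' @rdname write_outputs
#' @export
read_timeseries <- function(path) {
  read.csv(path, colClasses = "numeric")
}

#' @rdname write_outputs
#' @export
read_summary <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
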