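#' Loading protocol for the fibre simulation
#'
#' Builds the prescribed apparent strain path. The default emulates the
#' quasi-static cyclic micropillar protocol: a staircase of load-unload
#' cycles with increasing peak strains (1, 2, ..., 12 percent) and a full
#' unload between peaks, sampled at a strain resolution of 1e-4. Compressive
#' strain is taken positive throughout the package.
#'
#' @param peaks increasing vector of peak apparent strains (default
#'   `seq(0.01, 0.12, by = 0.01)`).
#' @param resolution strain increment between consecutive protocol points
#'   (default 1e-4).
#' @param unload_to strain to which each cycle unloads (default 0, full
#'   unload; the bundle cannot transmit tension, contact is unilateral).
#' @param cyclic if `FALSE` the path is a single monotone ramp to
#'   `max(peaks)`.
#' @param n_report number of evenly spaced report points along the path at
#'   which in-situ scattering read-outs would be taken (default 120).
#' @return An object of class `"loading_protocol"`: list with the strain
#'   `path`, the `peaks`, the `resolution`, the maximum strain and
#'   `report_idx`, the indices of the report points.
#' @export
#' @examples
#' pr <- make_protocol(peaks = 0.12, cyclic = FALSE)
#' range(pr$path)
make_protocol <- function(peaks = seq(0.01, 0.12, by = 0.01),
                          resolution = 1e-4, unload_to = 0, cyclic = TRUE,
                          n_report = 120) {
  stopifnot(length(peaks) >= 1, all(diff(peaks) > 0), resolution > 0,
            unload_to >= 0, unload_to < min(peaks))
  if (max(peaks) > 0.15)
    stop("peak strains above 0.15 are outside the intended protocol range")
  if (!cyclic) {
    path <- seq(0, max(peaks), by = resolution)
  } else {
    path <- 0
    from <- 0
    for (p in peaks) {
      up <- seq(from, p, by = resolution)
      down <- seq(p, unload_to, by = -resolution)
      path <- c(path, up[-1], down[-1])
      from <- unload_to
    }
    # finish reloaded at the final peak so end-of-run states refer to the
    # fully loaded configuration
    path <- c(path, seq(unload_to, max(peaks), by = resolution)[-1])
  }
  structure(list(path = path, peaks = peaks, resolution = resolution,
                 max_strain = max(peaks),
                 report_idx = unique(round(seq(1, length(path),
                                               length.out = min(n_report,
                                                                length(path)))))),
            class = "loading_protocol")
}

#' @export
print.loading_protocol <- function(x, ...) {
  cat(sprintf(
    "Loading protocol: %d points, peaks %s, resolution %g\n",
    length(x$path), paste(format(x$peaks), collapse = ", "), x$resolution))
  invisible(x)
}
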