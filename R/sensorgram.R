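#' Injection protocol for an SPR experiment
#'
#' Describes a single analyte injection: concentration, association and
#' dissociation durations, and the sampling interval. Defaults mirror a
#' typical kinetic titration on a biolayer/SPR instrument: two-minute
#' injections followed by 200 s of buffer wash, sampled once per second.
#' The flow rate is recorded metadata only; the kinetic model contains no
#' mass-transport term.
#'
#' @param concentration Analyte concentration during the injection (molar).
#' @param t_association Association-phase duration (s).
#' @param t_dissociation Dissociation-phase duration (s).
#' @param sampling_interval Time between samples (s).
#' @param flow_rate_ul_min Flow rate (uL/min), metadata only.
#' @return An object of class `injection_protocol`.
#' @export
injection_protocol <- function(concentration, t_association = 120,
                               t_dissociation = 200, sampling_interval = 1,
                               flow_rate_ul_min = 20) {
  if (concentration < 0)
    abort("analyte concentration must be >= 0", "protomer_domain_error")
  if (t_association <= 0 || t_dissociation <= 0 || sampling_interval <= 0)
    abort("durations and sampling interval must be > 0", "protomer_domain_error")
  structure(list(concentration = concentration,
                 t_association = t_association,
                 t_dissociation = t_dissociation,
                 sampling_interval = sampling_interval,
                 flow_rate_ul_min = flow_rate_ul_min),
            class = "injection_protocol")
}

#' @export
print.injection_protocol <- function(x, ...) {
  cat(sprintf(
    "Injection: %.4g M analyte, %g s association + %g s dissociation, dt = %g s\n",
    x$concentration, x$t_association, x$t_dissociation, x$sampling_interval))
  invisible(x)
}

protocol_times <- function(protocol) {
  seq(0, protocol$t_association + protocol$t_dissociation,
      by = protocol$sampling_interval)
}

#' Construct a sensorgram
#'
#' A sensorgram is the time course of surface response (in resonance units,
#' RU) during an analyte injection and the following buffer wash.
#'
#' @param time Sample times (s), strictly increasing, starting at 0.
#' @param response Surface response (RU), same length as `time`.
#' @param protocol The [injection_protocol()] that produced the curve.
#' @param species Optional matrix of underlying species amounts
#'   (columns `L`, `AL`, `AL2`, in RU), as returned by the simulator.
#' @return An object of class `sensorgram` (a data frame with columns
#'   `time` and `response` plus attributes).
#' @export
sensorgram <- function(time, response, protocol, species = NULL) {
  time <- as.numeric(time); response <- as.numeric(response)
  if (length(time) != length(response))
    abort("time and response must have the same length", "protomer_domain_error")
  if (length(time) < 2 || time[1] != 0 || any(diff(time) <= 0))
    abort("time must start at 0 and be strictly increasing",
          "protomer_domain_error")
  structure(data.frame(time = time, response = response),
            protocol = protocol, species = species,
            class = c("sensorgram", "data.frame"))
}

#' @export
print.sensorgram <- function(x, ...) {
  p <- attr(x, "protocol")
  cat(sprintf("Sensorgram: %d points, C = %.4g M, max response %.1f RU\n",
              nrow(x), p$concentration, max(x$response)))
  invisible(x)
}

#' @rdname sensorgram
#' @param x A `sensorgram` object.
#' @param ... Passed on to [graphics::lines()].
#' @export
plot.sensorgram <- function(x, ...) {
  plot(x$time, x$response, type = "l", xlab = "Time (s)",
       ylab = "Response (RU)", ...)
  abline(v = attr(x, "protocol")$t_association, lty = 3, col = "grey50")
  invisible(x)
}

#' Read and write sensorgram files
#'
#' Sensorgrams are exchanged as two-column delimited text
#' (`time_s,response_RU`), one file per injection. The analyte
#' concentration and phase boundaries travel in a separate manifest
#' (see [write_sensorgram_series()]).
#'
#' @param path File path.
#' @param protocol The [injection_protocol()] for the curve (required on
#'   read because the flat file carries no metadata).
#' @return `read_sensorgram()` returns a [sensorgram()];
#'   `write_sensorgram()` returns `path` invisibly.
#' @export
read_sensorgram <- function(path, protocol) {
  d <- read.csv(path)
  sensorgram(d[[1]], d[[2]], protocol)
}

#' @rdname read_sensorgram
#' @param sg A [sensorgram()] object.
#' @export
write_sensorgram <- function(sg, path) {
  write.csv(data.frame(time_s = sg$time, response_RU = sg$response),
            path, row.names = FALSE)
  invisible(path)
}

#' Write a concentration series with its manifest
#'
#' Writes one CSV per sensorgram plus a `manifest.csv` mapping file name to
#' concentration (M) and phase boundaries, the layout expected by
#' [read_sensorgram_series()].
#'
#' @param sensorgrams List of [sensorgram()] objects.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_sensorgram_series <- function(sensorgrams, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(sensorgrams), function(i) {
    sg <- sensorgrams[[i]]
    p <- attr(sg, "protocol")
    f <- sprintf("curve_%02d.csv", i)
    write_sensorgram(sg, file.path(dir, f))
    data.frame(file = f, concentration_M = p$concentration,
               t_association_s = p$t_association,
               t_dissociation_s = p$t_dissociation)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' @rdname write_sensorgram_series
#' @export
read_sensorgram_series <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    p <- injection_protocol(manifest$concentration_M[i],
                            manifest$t_association_s[i],
                            manifest$t_dissociation_s[i])
    read_sensorgram(file.path(dir, manifest$file[i]), p)
  })
}
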