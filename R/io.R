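# Plain-text and JSON I/O dialects: waveform files, encoding reports,
# spectra, protocols and signal datasets.

#' Write a waveform to a plain-text file
#'
#' Header lines `#tau_s`, `#dt_s`, `#gamma`, `#spec` (JSON), then four
#' columns `t gx gy gz` in SI units at 12 significant digits.
#'
#' @param w a `waveform_3d`.
#' @param path output file.
#' @export
write_waveform <- function(w, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#tau_s %.12g", w$tau),
               sprintf("#dt_s %.12g", w$dt),
               sprintf("#gamma %.12g", w$gamma),
               paste("#spec", if (is.null(w$spec)) "{}" else
                 jsonlite::toJSON(w$spec[!vapply(w$spec, is.null, TRUE)],
                                  auto_unbox = TRUE, digits = NA)),
               "#t gx gy gz"), con)
  writeLines(sprintf("%.12g %.12g %.12g %.12g",
                     w$t, w$g[, 1], w$g[, 2], w$g[, 3]), con)
  invisible(path)
}

#' Read a waveform written by [write_waveform()]
#'
#' The dephasing trajectory is recomputed from the gradient samples.
#'
#' @param path input file.
#' @return A `waveform_3d`.
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  val <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, " "))]
    sub(paste0("^#", key, " "), "", ln[1])
  }
  gamma <- as.numeric(val("gamma"))
  spec_json <- val("spec")
  spec <- if (!is.na(spec_json) && nzchar(spec_json) && spec_json != "{}") {
    sp <- jsonlite::fromJSON(spec_json)
    class(sp) <- "dor_spec"
    sp
  } else NULL
  dat <- utils::read.table(text = lines[!startsWith(lines, "#")])
  t <- dat[[1]]
  g <- as.matrix(dat[, 2:4])
  dimnames(g) <- NULL
  dt <- t[2] - t[1]
  q <- apply(g, 2, function(gc) gamma * cumtrapz(gc, dt))
  structure(list(t = t, g = g, q = q, dt = dt, tau = t[length(t)],
                 gamma = gamma, spec = spec,
                 orientation = c(theta = 0, phi = 0)),
            class = "waveform_3d")
}

#' JSON encoding report for a waveform
#'
#' Writes `{b, b_delta, b_eta, omega_cent_Hz, q_v, eigenvalues}`.
#'
#' @param w a `waveform_3d` (or a precomputed [btensor()]).
#' @param path output file.
#' @export
write_report <- function(w, path) {
  bt <- if (inherits(w, "btensor")) w else btensor(w)
  rep <- list(b = bt$b, b_delta = bt$b_delta, b_eta = bt$b_eta,
              omega_cent_Hz = bt$omega_cent / (2 * pi),
              q_v = bt$q_v, eigenvalues = as.list(bt$eigenvalues))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export an encoding spectrum as delimited text
#'
#' Columns: frequency in Hz, the six independent real elements of
#' `b(omega)` (xx, yy, zz, xy, xz, yz) and the trace.
#'
#' @param es an `encoding_spectrum`.
#' @param path output file.
#' @param omega_max truncate the export at this frequency (rad/s).
#' @export
write_spectrum <- function(es, path, omega_max = NULL) {
  keep <- if (is.null(omega_max)) seq_along(es$omega) else
    which(es$omega <= omega_max)
  Q <- es$Q[keep, , drop = FALSE]
  bxx <- Mod(Q[, 1])^2; byy <- Mod(Q[, 2])^2; bzz <- Mod(Q[, 3])^2
  bxy <- Re(Q[, 1] * Conj(Q[, 2])); bxz <- Re(Q[, 1] * Conj(Q[, 3]))
  byz <- Re(Q[, 2] * Conj(Q[, 3]))
  m <- cbind(es$omega[keep] / (2 * pi), bxx, byy, bzz, bxy, bxz, byz,
             bxx + byy + bzz) / (2 * pi)
  m[, 1] <- es$omega[keep] / (2 * pi)
  utils::write.table(
    stats::setNames(as.data.frame(m),
                    c("omega_Hz", "bxx", "byy", "bzz", "bxy", "bxz", "byz",
                      "trace")),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write/read a signal dataset as CSV
#'
#' Columns: `waveform_id, b, bdelta_nominal, omega_cent_Hz, theta_deg,
#' phi_deg, S, S0` (plus any extras present).
#'
#' @param ds dataset data.frame.
#' @param path file path.
#' @export
write_dataset <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  ds <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(ds) <- c("dor_dataset", "data.frame")
  ds
}

#' Write/read protocol metadata as JSON
#'
#' Serializes the waveform specification list together with the b shells
#' and orientations; the sampled waveforms and spectra are regenerated with
#' [build_protocol()] on reading.
#'
#' @param protocol a `dor_protocol`.
#' @param path file path.
#' @export
write_protocol <- function(protocol, path) {
  obj <- list(tau = protocol$tau, gamma = protocol$gamma,
              g_max = protocol$g_max, b_max = protocol$b_max,
              b_values = protocol$b_values,
              orientations = protocol$orientations,
              waveforms = protocol$waveforms,
              specs = lapply(protocol$specs, function(s)
                s[!vapply(s, is.null, TRUE)]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
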