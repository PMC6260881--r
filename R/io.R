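#' Read and write signal tables
#'
#' Signals travel as delimited text, one column per record, optional
#' header. `read_signals()` returns a numeric matrix (columns = records);
#' `write_signals()` writes one.
#'
#' @param path File path.
#' @param sep Field separator; `","` for CSV (default), `"\t"` for TSV.
#' @param header Whether the file carries column names.
#' @return `read_signals()`: numeric matrix with one column per record.
#' @export
read_signals <- function(path, sep = ",", header = TRUE) {
  df <- utils::read.table(path, sep = sep, header = header)
  as.matrix(df)
}

#' @rdname read_signals
#' @param x Numeric matrix or vector of signal samples.
#' @export
write_signals <- function(x, path, sep = ",") {
  x <- as.matrix(x)
  utils::write.table(x, path, sep = sep, row.names = FALSE,
                     col.names = !is.null(colnames(x)), quote = FALSE)
  invisible(path)
}

#' Serialize a Prony decomposition to JSON
#'
#' One JSON object per component with fields `amp`, `alpha_per_s`,
#' `freq_hz`, `phase_rad`, `pole_re`, `pole_im`, `h_re`, `h_im`, plus a
#' header with `ts`, `method` and `order`. The `-Inf` damping sentinel of
#' zero poles is written as the string `"-inf"`.
#'
#' @param object A [prony_fit] object or component tibble.
#' @param path Output file path.
#' @param ts,method,order Metadata when `object` is a bare component table.
#' @export
write_decomposition <- function(object, path, ts = NULL, method = NULL,
                                order = NULL) {
  comps <- as_components(object)
  if (inherits(object, "prony_fit")) {
    ts <- ts %||% object$ts
    method <- method %||% object$method
    order <- order %||% object$order
  }
  alpha <- as.list(comps$damping)
  alpha <- lapply(alpha, function(a) if (is.infinite(a) && a < 0) "-inf" else a)
  payload <- list(
    ts = ts, method = method, order = order,
    components = purrr::pmap(
      list(comps$amp, alpha, comps$freq, comps$phase,
           Re(comps$pole), Im(comps$pole), Re(comps$weight),
           Im(comps$weight)),
      function(amp, alpha_per_s, freq_hz, phase_rad, pole_re, pole_im,
               h_re, h_im) {
        list(amp = amp, alpha_per_s = alpha_per_s, freq_hz = freq_hz,
             phase_rad = phase_rad, pole_re = pole_re, pole_im = pole_im,
             h_re = h_re, h_im = h_im)
      }
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Prony decomposition from JSON
#'
#' Inverse of [write_decomposition()].
#'
#' @param path JSON file path.
#' @return A component tibble (see [prony_components()]) with attributes
#'   `ts`, `method`, `order`.
#' @export
read_decomposition <- function(path) {
  payload <- jsonlite::read_json(path)
  comps <- purrr::map_dfr(payload$components, function(cp) {
    alpha <- cp$alpha_per_s
    if (identical(alpha, "-inf")) alpha <- -Inf
    tibble(
      amp = as.numeric(cp$amp),
      damping = as.numeric(alpha),
      freq = as.numeric(cp$freq_hz),
      phase = as.numeric(cp$phase_rad),
      pole = complex(real = as.numeric(cp$pole_re),
                     imaginary = as.numeric(cp$pole_im)),
      weight = complex(real = as.numeric(cp$h_re),
                       imaginary = as.numeric(cp$h_im)),
      zero_pole = identical(cp$alpha_per_s, "-inf")
    )
  })
  attr(comps, "ts") <- payload$ts
  attr(comps, "method") <- payload$method
  attr(comps, "order") <- payload$order
  comps
}
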