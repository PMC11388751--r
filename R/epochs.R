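# Epoch matrices: construction, segmentation, synthetic generation, I/O.

ECG_CLASSES <- c("VT", "PVC", "ST", "NSR")

#' Epoch matrix
#'
#' Container for fixed-length ECG epochs: one epoch per row, with a common
#' sampling rate and a class label per epoch. Arrhythmia classes (VT, PVC,
#' ST) use 360-sample epochs at 360 Hz; normal sinus rhythm (NSR) uses
#' 128-sample epochs at 128 Hz.
#'
#' @param data numeric matrix, one epoch per row
#' @param fs sampling frequency in Hz (> 0)
#' @param labels character vector of per-epoch class tags, one of
#'   `"VT"`, `"PVC"`, `"ST"`, `"NSR"`
#' @param provenance free-text source tag
#' @return an object of class `epoch_matrix` with fields `data`,
#'   `epoch_length`, `fs`, `labels`, `provenance`
#' @export
epoch_matrix <- function(data, fs, labels, provenance = "unspecified") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  labels <- as.character(labels)
  if (nrow(data) == 0L) stop_ecgarr("epoch matrix must have at least one epoch")
  if (length(labels) != nrow(data)) {
    stop_ecgarr("labels must have one entry per epoch (",
                length(labels), " labels for ", nrow(data), " epochs)")
  }
  bad <- setdiff(unique(labels), ECG_CLASSES)
  if (length(bad)) stop_ecgarr("unknown class label(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_ecgarr("fs must be a single positive number")
  }
  structure(
    list(data = data, epoch_length = ncol(data), fs = fs,
         labels = labels, provenance = provenance),
    class = "epoch_matrix"
  )
}

#' @export
print.epoch_matrix <- function(x, ...) {
  cat("<epoch_matrix> ", nrow(x$data), " epochs x ", x$epoch_length,
      " samples @ ", x$fs, " Hz\n", sep = "")
  cat("  classes: ", paste(sprintf("%s=%d", names(table(x$labels)),
                                   table(x$labels)), collapse = ", "), "\n", sep = "")
  cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
dim.epoch_matrix <- function(x) dim(x$data)

#' Segment a continuous signal into fixed-length epochs
#'
#' Slices a sample sequence into consecutive, non-overlapping epochs of
#' `epoch_length` samples. Any trailing partial epoch is discarded, so the
#' result has `floor(length(signal) / epoch_length)` rows.
#'
#' @param signal numeric sample sequence
#' @param epoch_length samples per epoch
#' @param fs sampling frequency in Hz
#' @param label class tag applied to every epoch
#' @param provenance free-text source tag
#' @return an [epoch_matrix()]
#' @examples
#' em <- segment_into_epochs(sin(seq_len(1000) / 10), 360, 360, "VT")
#' nrow(em$data) # 2 epochs, 280 trailing samples discarded
#' @export
segment_into_epochs <- function(signal, epoch_length, fs, label,
                                provenance = "segmented") {
  signal <- as.numeric(signal)
  if (!is.numeric(epoch_length) || epoch_length < 1) {
    stop_ecgarr("epoch_length must be a positive integer")
  }
  epoch_length <- as.integer(epoch_length)
  if (length(signal) < epoch_length) {
    stop_ecgarr("signal (", length(signal), " samples) is shorter than one epoch (",
                epoch_length, " samples)")
  }
  n <- length(signal) %/% epoch_length
  m <- matrix(signal[seq_len(n * epoch_length)], nrow = n, ncol = epoch_length,
              byrow = TRUE)
  epoch_matrix(m, fs = fs, labels = rep(label, n), provenance = provenance)
}

#' Synthetic-generation configuration
#'
#' Parameters for [generate_synthetic_ecg()]. The defaults encode the
#' per-class study conditions: arrhythmia classes at 360 Hz with 360-sample
#' epochs, normal sinus rhythm at 128 Hz with 128-sample epochs, and
#' class-specific beat rate, morphology and distortion so that classes are
#' learnably separable without being trivially so.
#'
#' @param class_label one of `"VT"`, `"PVC"`, `"ST"`, `"NSR"`
#' @param n_epochs number of epochs to generate (>= 1)
#' @param seed integer RNG seed; the generator is a pure function of the
#'   full configuration including this seed
#' @param noise_sd baseline additive Gaussian noise level, in units of the
#'   R-wave amplitude (default 0.25). Each epoch additionally draws a
#'   log-normal noise multiplier (sdlog 0.5) so a minority of epochs are
#'   heavily artifact-corrupted, as in ambulatory recordings.
#' @param beat_rate beats per minute; class default if `NULL`
#'   (NSR/ST 75, PVC 80, VT 190)
#' @param amplitudes named numeric vector with components `P`, `QRS`, `T`
#'   scaling the three waveform bumps; class default if `NULL`
#' @param distortion arrhythmia distortion strength in `[0, 1]`; class
#'   default if `NULL` (0 for NSR)
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(class_label, n_epochs, seed = 1L,
                             noise_sd = 0.25, beat_rate = NULL,
                             amplitudes = NULL, distortion = NULL) {
  class_label <- match.arg(class_label, ECG_CLASSES)
  if (!is.numeric(n_epochs) || n_epochs < 1) stop_ecgarr("n_epochs must be >= 1")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_ecgarr("noise_sd must be >= 0")
  defaults <- switch(class_label,
    NSR = list(rate = 75,  amp = c(P = 0.15, QRS = 1.00, T = 0.30), dist = 0.00),
    VT  = list(rate = 190, amp = c(P = 0.00, QRS = 1.50, T = 0.40), dist = 0.30),
    PVC = list(rate = 80,  amp = c(P = 0.15, QRS = 1.00, T = 0.30), dist = 0.50),
    ST  = list(rate = 75,  amp = c(P = 0.15, QRS = 1.00, T = 0.30), dist = 0.20))
  beat_rate <- beat_rate %||% defaults$rate
  if (beat_rate <= 0) stop_ecgarr("beat_rate must be > 0")
  structure(
    list(class_label = class_label, n_epochs = as.integer(n_epochs),
         seed = as.integer(seed), noise_sd = noise_sd, beat_rate = beat_rate,
         amplitudes = amplitudes %||% defaults$amp,
         distortion = distortion %||% defaults$dist),
    class = "synthetic_config"
  )
}

# One beat template on phase grid u in [0,1): sum of Gaussian bumps for the
# P wave, QRS complex (Q, R, S) and T wave. `widen` broadens the QRS (VT,
# ectopic beats); `st_offset` raises the ST segment between S and T.
beat_template <- function(u, amp, widen = 1, st_offset = 0, invert_qrs = FALSE) {
  g <- function(center, width, a) a * exp(-0.5 * ((u - center) / width)^2)
  qrs_sign <- if (invert_qrs) -1 else 1
  y <- g(0.20, 0.030, amp[["P"]]) +
    qrs_sign * (g(0.47, 0.020 * widen, -0.12 * amp[["QRS"]]) +
                g(0.50, 0.014 * widen,  1.00 * amp[["QRS"]]) +
                g(0.53, 0.020 * widen, -0.18 * amp[["QRS"]])) +
    g(0.72, 0.055, amp[["T"]])
  if (st_offset != 0) {
    y <- y + st_offset * exp(-0.5 * ((u - 0.62) / 0.05)^2)
  }
  y
}

#' Generate synthetic ECG-like epochs
#'
#' Draws `n_epochs` epochs of a sum-of-Gaussians beat train (P/QRS/T bumps)
#' with class-specific rate, morphology and distortion, plus additive
#' Gaussian noise whose level varies per epoch. VT epochs have a fast,
#' wide-QRS, P-free morphology; PVC epochs contain one wide inverted
#' ectopic beat; ST epochs carry an elevated ST segment; NSR is the clean
#' baseline. The generator is deterministic given the configuration
#' (including its seed) and does not perturb the caller's RNG state.
#'
#' @param config a [synthetic_config()]
#' @return an [epoch_matrix()] (128 samples at 128 Hz for NSR, 360 samples
#'   at 360 Hz otherwise)
#' @examples
#' em <- generate_synthetic_ecg(synthetic_config("NSR", 10, seed = 42))
#' dim(em$data) # 10 x 128
#' @export
generate_synthetic_ecg <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop_ecgarr("config must be created with synthetic_config()")
  }
  fs <- if (config$class_label == "NSR") 128 else 360
  len <- fs # one-second epochs
  with_seed(config$seed, {
    m <- matrix(0, nrow = config$n_epochs, ncol = len)
    tt <- seq(0, by = 1 / fs, length.out = len)
    for (i in seq_len(config$n_epochs)) {
      rate <- config$beat_rate * exp(stats::rnorm(1, 0, 0.05))
      period <- 60 / rate
      phase0 <- stats::runif(1)
      amp <- config$amplitudes * exp(stats::rnorm(3, 0, 0.10))
      # VT is a wide-complex, near-sinusoidal rhythm: broaden the QRS a lot
      widen <- 1 + 8 * config$distortion * (config$class_label == "VT")
      st_offset <- if (config$class_label == "ST") 1.2 * config$distortion else 0
      beat_idx <- floor(tt / period + phase0)
      u <- (tt / period + phase0) %% 1
      y <- beat_template(u, amp, widen = widen, st_offset = st_offset)
      if (config$class_label == "PVC" && config$distortion > 0) {
        # one ectopic beat per epoch: wide, inverted QRS, no P
        ect <- beat_idx == sample(unique(beat_idx), 1)
        amp_e <- amp
        amp_e[["P"]] <- 0
        y[ect] <- beat_template(u[ect], amp_e, widen = 1 + 3 * config$distortion,
                                invert_qrs = TRUE)
      }
      noise_mult <- exp(stats::rnorm(1, 0, 0.5))
      y <- y + stats::rnorm(len, 0, config$noise_sd * noise_mult)
      m[i, ] <- y
    }
    epoch_matrix(m, fs = fs, labels = rep(config$class_label, config$n_epochs),
                 provenance = sprintf("synthetic(%s, seed=%d, contiguous)",
                                      config$class_label, config$seed))
  })
}

#' Write an epoch matrix to CSV
#'
#' The file carries metadata header lines (`# key: value` for `fs`,
#' `epoch_length` and `provenance`) followed by a CSV table with a `label`
#' column and one column per sample. [read_epoch_matrix()] round-trips the
#' result exactly.
#'
#' @param matrix an [epoch_matrix()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_epoch_matrix <- function(matrix, path) {
  if (!inherits(matrix, "epoch_matrix")) stop_ecgarr("not an epoch_matrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# ecgarr epoch matrix",
    sprintf("# fs: %.10g", matrix$fs),
    sprintf("# epoch_length: %d", matrix$epoch_length),
    sprintf("# provenance: %s", matrix$provenance)
  ), con)
  # %.17g guarantees an exact double round-trip
  vals <- matrix(sprintf("%.17g", matrix$data), nrow = nrow(matrix$data))
  writeLines(paste(c("label", sprintf("s%d", seq_len(matrix$epoch_length))),
                   collapse = ","), con)
  writeLines(paste(matrix$labels, apply(vals, 1, paste, collapse = ","),
                   sep = ","), con)
  invisible(path)
}

#' Read an epoch matrix from CSV
#'
#' Reads the format written by [write_epoch_matrix()]. Malformed headers,
#' ragged rows and unknown labels are rejected with the offending line
#' number.
#'
#' @param path input file path
#' @return an [epoch_matrix()]
#' @export
read_epoch_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop_ecgarr("empty file: ", path)
  hdr <- grep("^#", lines)
  if (length(hdr) == 0L || any(diff(hdr) != 1L) || hdr[1] != 1L) {
    stop_ecgarr("malformed header in ", path,
                ": expected leading '# key: value' lines")
  }
  get_meta <- function(key) {
    ln <- grep(sprintf("^# %s:", key), lines[hdr], value = TRUE)
    if (length(ln) != 1L) stop_ecgarr("missing '# ", key, ":' header line in ", path)
    sub(sprintf("^# %s:\\s*", key), "", ln)
  }
  fs <- suppressWarnings(as.numeric(get_meta("fs")))
  epoch_length <- suppressWarnings(as.integer(get_meta("epoch_length")))
  provenance <- get_meta("provenance")
  if (is.na(fs) || is.na(epoch_length)) {
    stop_ecgarr("malformed header in ", path, ": fs/epoch_length not numeric")
  }
  body <- lines[-hdr]
  if (length(body) < 2L) stop_ecgarr("no epoch rows in ", path)
  cols <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (cols[1] != "label" || length(cols) != epoch_length + 1L) {
    stop_ecgarr("malformed column header at line ", length(hdr) + 1L, " in ", path)
  }
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  labels <- character(length(rows))
  m <- matrix(NA_real_, nrow = length(rows), ncol = epoch_length)
  for (i in seq_along(rows)) {
    line_no <- length(hdr) + 1L + i
    r <- rows[[i]]
    if (length(r) != epoch_length + 1L) {
      stop_ecgarr("row at line ", line_no, " has ", length(r) - 1L,
                  " values; expected ", epoch_length)
    }
    if (!(r[1] %in% ECG_CLASSES)) {
      stop_ecgarr("unknown label '", r[1], "' at line ", line_no)
    }
    vals <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(vals)) stop_ecgarr("non-numeric sample at line ", line_no)
    labels[i] <- r[1]
    m[i, ] <- vals
  }
  epoch_matrix(m, fs = fs, labels = labels, provenance = provenance)
}
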