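#' Continuous-signal preprocessing
#'
#' Zero-phase Butterworth band-pass filtering, epoching with baseline
#' correction, deterministic amplitude-based artifact rejection, and grand
#' averaging.
#'
#' @name preprocess
NULL

#' Preprocessing parameters
#'
#' @param band band-pass edges in Hz (default 0.5-40).
#' @param filter_order Butterworth order per pass and per edge (default 2,
#'   i.e. a -12 dB/oct roll-off per pass).
#' @param epoch_ms epoch limits in ms relative to stimulus onset.
#' @param baseline_ms baseline window in ms (half-open, `[start, end)`).
#' @param reject_peak_to_peak_uV rejection threshold: an epoch is dropped if
#'   any channel's peak-to-peak amplitude exceeds this value (microvolts).
#' @return an object of class `preproc_params`.
#' @export
preproc_params <- function(band = c(0.5, 40), filter_order = 2L,
                           epoch_ms = c(-100, 700),
                           baseline_ms = c(-100, 0),
                           reject_peak_to_peak_uV = 150) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1]) {
    stop("band must be (low, high) with 0 < low < high")
  }
  if (filter_order < 1L) stop("filter_order must be >= 1")
  if (reject_peak_to_peak_uV <= 0) stop("rejection threshold must be > 0")
  structure(list(band = band, filter_order = as.integer(filter_order),
                 epoch_ms = epoch_ms, baseline_ms = baseline_ms,
                 reject_peak_to_peak_uV = reject_peak_to_peak_uV),
            class = "preproc_params")
}

# round-half-up; base round() rounds half to even
.round_half_up <- function(x) floor(x + 0.5)

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass (coefficients from [signal::butter()])
#' in two passes, one forward and one backward, eliminating the phase shift;
#' the effective magnitude response is the squared single-pass response.
#' Channel means (DC) are removed first, and the signal is extended by odd
#' reflection before filtering to suppress edge transients; the extension is
#' three times the filter's effective impulse-response length (bounded by
#' the signal length).
#'
#' @param x channels-by-samples numeric matrix, or an `evoked_erp`.
#' @param sfreq sampling rate in Hz (taken from the object if an
#'   `evoked_erp` is given).
#' @param params a `preproc_params`.
#' @return the filtered object, same type as `x`.
#' @export
bandpass_filter <- function(x, sfreq = NULL, params = preproc_params()) {
  if (inherits(x, "evoked_erp")) {
    x$data <- bandpass_filter(x$data, x$sfreq, params)
    return(x)
  }
  x <- as.matrix(x)
  nyq <- sfreq / 2
  if (params$band[2] >= nyq) {
    stop("band edge at or above the Nyquist frequency")
  }
  n <- ncol(x)
  if (n <= 3L * params$filter_order) {
    stop("signal too short for the requested filter order")
  }
  bf <- signal::butter(params$filter_order, params$band / nyq, type = "pass")
  # effective impulse-response length ~ one period of the slow band edge
  pad <- min(n - 1L, 3L * ceiling(sfreq / params$band[1]))
  x <- x - rowMeans(x)
  out <- t(apply(x, 1L, function(ch) {
    ext <- c(2 * ch[1] - ch[(pad + 1L):2L],
             ch,
             2 * ch[n] - ch[(n - 1L):(n - pad)])
    y <- signal::filter(bf, ext)
    y <- rev(signal::filter(bf, rev(y)))
    y[(pad + 1L):(pad + n)]
  }))
  dimnames(out) <- dimnames(x)
  out
}

#' Extract stimulus-locked epochs with baseline correction
#'
#' Epochs span the configured window relative to each event (half-open
#' `[start, end)`, sample count = round-half-up of duration x sfreq); the
#' per-channel mean over the baseline window is subtracted. Events too close
#' to the record edge are skipped with a warning.
#'
#' @param continuous channels-by-samples numeric matrix.
#' @param events 1-based sample indices of stimulus onsets.
#' @param sfreq sampling rate in Hz.
#' @param params a `preproc_params`.
#' @return a list of baseline-corrected epoch matrices.
#' @export
epoch_and_baseline <- function(continuous, events, sfreq,
                               params = preproc_params()) {
  continuous <- as.matrix(continuous)
  n <- ncol(continuous)
  off0 <- .round_half_up(params$epoch_ms[1] / 1000 * sfreq)
  nsamp <- .round_half_up((params$epoch_ms[2] - params$epoch_ms[1]) / 1000 * sfreq)
  tms <- (off0 + seq_len(nsamp) - 1L) / sfreq * 1000
  bl <- tms >= params$baseline_ms[1] & tms < params$baseline_ms[2]
  out <- list()
  for (ev in events) {
    i0 <- ev + off0
    if (i0 < 1L || i0 + nsamp - 1L > n) {
      warning(sprintf("event at sample %d too close to the record edge; skipped",
                      ev))
      next
    }
    ep <- continuous[, i0:(i0 + nsamp - 1L), drop = FALSE]
    if (any(bl)) ep <- ep - rowMeans(ep[, bl, drop = FALSE])
    out[[length(out) + 1L]] <- ep
  }
  out
}

#' Amplitude-based artifact rejection
#'
#' Deterministic stand-in for visual artifact screening: an epoch is dropped
#' if and only if any channel's peak-to-peak amplitude exceeds the
#' threshold.
#'
#' @param epochs list of channels-by-samples epoch matrices.
#' @param params a `preproc_params` (uses `reject_peak_to_peak_uV`).
#' @return a list with `retained` (the surviving epochs) and `log`
#'   (data.frame: epoch index, worst channel, its peak-to-peak amplitude,
#'   rejected flag).
#' @export
reject_artifacts <- function(epochs, params = preproc_params()) {
  thr <- params$reject_peak_to_peak_uV
  log <- do.call(rbind, lapply(seq_along(epochs), function(i) {
    ptp <- apply(epochs[[i]], 1L, function(ch) max(ch) - min(ch))
    w <- which.max(ptp)
    data.frame(epoch = i,
               channel = if (!is.null(rownames(epochs[[i]])))
                 rownames(epochs[[i]])[w] else as.character(w),
               max_ptp_uV = ptp[w],
               rejected = ptp[w] > thr,
               stringsAsFactors = FALSE)
  }))
  list(retained = epochs[!log$rejected], log = log)
}

#' Grand average of per-subject evoked ERPs
#'
#' Unweighted mean across subjects of one condition's evoked responses.
#'
#' @param erps list of `evoked_erp` with identical dimensions, sampling
#'   rate and epoch origin.
#' @return an `evoked_erp` with `subject_id = "grand_average"`.
#' @export
grand_average <- function(erps) {
  if (length(erps) == 0L) stop("no ERPs to average")
  ref <- erps[[1L]]
  for (e in erps) {
    if (!identical(dim(e$data), dim(ref$data)) ||
        e$sfreq != ref$sfreq || e$t0_ms != ref$t0_ms) {
      stop("grand average requires identical montage, sfreq and epoch")
    }
  }
  acc <- Reduce(`+`, lapply(erps, `[[`, "data")) / length(erps)
  out <- ref
  out$data <- acc
  out$subject_id <- "grand_average"
  out$is_avg_ref <- all(vapply(erps, `[[`, logical(1), "is_avg_ref"))
  out
}
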