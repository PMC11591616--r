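#' Reference-free topographic primitives
#'
#' Scalp-field measures used throughout the package: the average reference,
#' global field power (GFP), strength-independent spatial correlation, and
#' GFP normalization of template maps. All of these are invariant to the
#' recording reference because they operate on the channel-demeaned field.
#'
#' @name topography
NULL

.tol_zero_gfp <- 1e-12

#' Construct an evoked ERP object
#'
#' An `evoked_erp` holds a channels-by-samples voltage matrix (microvolts)
#' together with its sampling rate, epoch origin and design labels
#' (subject, language L1/L2, embodiment motor/non-motor).
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param sfreq sampling frequency in Hz.
#' @param t0_ms time of the first sample relative to stimulus onset in ms
#'   (negative values indicate a pre-stimulus baseline).
#' @param subject_id subject identifier.
#' @param language `"L1"` or `"L2"`.
#' @param embodiment `"motor"` or `"non-motor"`.
#' @param channel_names optional channel labels (defaults to rownames).
#' @return an object of class `evoked_erp`.
#' @export
evoked_erp <- function(data, sfreq, t0_ms,
                       subject_id = NA_character_,
                       language = NA_character_,
                       embodiment = NA_character_,
                       channel_names = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    stop("ERP data must be a finite numeric matrix (channels x samples)")
  }
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0) {
    stop("sfreq must be a positive scalar (Hz)")
  }
  if (length(language) != 1L) language <- NA_character_
  if (length(embodiment) != 1L) embodiment <- NA_character_
  if (length(subject_id) != 1L) subject_id <- NA_character_
  if (!is.na(language) && !language %in% c("L1", "L2")) {
    stop("language must be 'L1' or 'L2'")
  }
  if (!is.na(embodiment) && !embodiment %in% c("motor", "non-motor")) {
    stop("embodiment must be 'motor' or 'non-motor'")
  }
  if (!is.null(channel_names)) {
    rownames(data) <- channel_names
  }
  structure(
    list(data = data, sfreq = sfreq, t0_ms = t0_ms,
         subject_id = subject_id, language = language,
         embodiment = embodiment, is_avg_ref = FALSE),
    class = "evoked_erp")
}

#' @export
print.evoked_erp <- function(x, ...) {
  tms <- erp_times(x)
  cat(sprintf(
    "<evoked_erp> %d channels x %d samples @ %g Hz, %g..%g ms\n",
    nrow(x$data), ncol(x$data), x$sfreq, tms[1], tms[length(tms)]))
  cat(sprintf("  subject: %s  language: %s  embodiment: %s  avg-ref: %s\n",
              x$subject_id, x$language, x$embodiment, x$is_avg_ref))
  invisible(x)
}

#' Sample times of an evoked ERP
#'
#' @param erp an `evoked_erp`.
#' @return numeric vector of sample times in ms relative to stimulus onset.
#' @export
erp_times <- function(erp) {
  erp$t0_ms + (seq_len(ncol(erp$data)) - 1L) / erp$sfreq * 1000
}

#' Re-reference to the average reference
#'
#' Subtracts the instantaneous channel mean from every time sample so that
#' every column of the data matrix sums to zero. Topographic measures are
#' only reference-free on average-referenced data. The operation is
#' idempotent.
#'
#' @param x an `evoked_erp` or a channels-by-samples numeric matrix.
#' @return the same type of object, average-referenced.
#' @export
average_reference <- function(x) {
  if (inherits(x, "evoked_erp")) {
    x$data <- average_reference(x$data)
    x$is_avg_ref <- TRUE
    return(x)
  }
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("cannot average-reference non-finite data")
  sweep(x, 2L, colMeans(x), "-")
}

#' Global field power
#'
#' The GFP of a scalp map is the spatial standard deviation of the field
#' across channels, using the population (1/N) normalization:
#' `GFP(u) = sqrt(mean((u - mean(u))^2))`. It is reference-free and
#' scale-equivariant (`GFP(c*u) = |c|*GFP(u)`).
#'
#' @param x a numeric map vector, a channels-by-samples matrix, or an
#'   `evoked_erp`.
#' @return a scalar for a single map, otherwise a per-sample numeric vector.
#' @export
gfp <- function(x) {
  if (inherits(x, "evoked_erp")) x <- x$data
  if (is.matrix(x)) {
    if (nrow(x) < 2L) stop("GFP is undefined for a single channel")
    xc <- sweep(x, 2L, colMeans(x), "-")
    return(sqrt(colMeans(xc^2)))
  }
  x <- as.numeric(x)
  if (length(x) < 2L) stop("GFP is undefined for a single channel")
  sqrt(mean((x - mean(x))^2))
}

#' Strength-independent spatial correlation between two maps
#'
#' Pearson correlation across channels of the average-referenced maps.
#' Invariant to positive rescaling of either map and to any change of the
#' recording reference; polarity-sensitive (the sign is preserved), as is
#' conventional for latency-locked evoked responses.
#'
#' @param u,v numeric map vectors over the same montage.
#' @return a scalar in `[-1, 1]`.
#' @export
spatial_correlation <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) stop("maps must share the montage")
  u <- u - mean(u); v <- v - mean(v)
  gu <- sqrt(mean(u^2)); gv <- sqrt(mean(v^2))
  if (gu <= .tol_zero_gfp || gv <= .tol_zero_gfp) {
    stop("spatial correlation is undefined for a zero-GFP map")
  }
  max(-1, min(1, mean(u * v) / (gu * gv)))
}

#' Normalize a map to zero mean and unit GFP
#'
#' Template maps are represented as zero-mean, unit-GFP channel vectors so
#' that clustering and back-fitting see only the field configuration, never
#' its strength.
#'
#' @param u numeric map vector with non-zero GFP.
#' @return a numeric vector with channel mean 0 and GFP 1.
#' @export
normalize_map <- function(u) {
  u <- as.numeric(u)
  u <- u - mean(u)
  g <- sqrt(mean(u^2))
  if (g <= .tol_zero_gfp) stop("cannot normalize a zero-GFP map")
  u / g
}

# Columns of `x` demeaned and scaled to unit GFP; zero-GFP columns -> NA.
# Internal workhorse for clustering/back-fitting.
.normalize_columns <- function(x) {
  xc <- sweep(x, 2L, colMeans(x), "-")
  g <- sqrt(colMeans(xc^2))
  ok <- g > .tol_zero_gfp
  xn <- sweep(xc, 2L, pmax(g, .tol_zero_gfp), "/")
  xn[, !ok] <- NA_real_
  list(maps = xn, gfp = g, ok = ok)
}
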