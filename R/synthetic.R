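#' Synthetic multi-condition ERP data with planted microstate structure
#'
#' A generator for 2 x 2 (language L1/L2 x embodiment motor/non-motor)
#' multi-subject evoked datasets in which a known sequence of template
#' topographies occupies known time windows, so that segmentation,
#' back-fitting and the repeated-measures ANOVA can be validated against
#' ground truth.
#'
#' @name synthetic_data
NULL

.cells <- function() {
  data.frame(language = rep(c("L1", "L2"), each = 2L),
             embodiment = rep(c("motor", "non-motor"), 2L),
             stringsAsFactors = FALSE)
}

.cell_key <- function(language, embodiment) paste(language, embodiment, sep = ".")

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so the generator never perturbs user code.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for a labelled stream, kept inside 32-bit range.
.sub_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(p) {
    utf8ToInt(paste0(as.character(p), collapse = "/"))
  }))
  h <- as.double(seed) %% 2147483647
  for (p in parts) h <- (h * 31 + p) %% 2147483647
  as.integer(h)
}

#' Construct a montage
#'
#' @param labels character vector of unique channel names.
#' @param positions numeric matrix (n x 3) of unit-sphere coordinates.
#' @return an object of class `montage`.
#' @export
montage <- function(labels, positions) {
  positions <- as.matrix(positions)
  if (anyDuplicated(labels)) stop("duplicate channel labels in montage")
  if (length(labels) != nrow(positions) || ncol(positions) != 3L) {
    stop("positions must be an n x 3 matrix matching labels")
  }
  nrm <- sqrt(rowSums(positions^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("montage positions must have unit norm (within 1e-6)")
  }
  structure(list(labels = as.character(labels), positions = positions,
                 n_channels = length(labels)),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels on the unit sphere\n", x$n_channels))
  invisible(x)
}

#' Generate a quasi-uniform upper-hemisphere montage
#'
#' Places `n_channels` electrodes on the upper hemisphere of the unit sphere
#' using a Fibonacci lattice, rotated about the vertical axis by a
#' seed-dependent angle. Deterministic for a given seed.
#'
#' @param n_channels number of electrodes (at least 8).
#' @param seed RNG seed controlling the lattice rotation.
#' @return a `montage`.
#' @export
make_montage <- function(n_channels = 128L, seed = 1L) {
  if (n_channels < 8L) stop("a montage needs at least 8 channels")
  phi0 <- .with_seed(.sub_seed(seed, "montage"), stats::runif(1, 0, 2 * pi))
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n_channels) - 1L
  # z from just above the equatorial rim to near the vertex: upper hemisphere
  z <- 0.02 + (i + 0.5) / n_channels * 0.97
  r <- sqrt(pmax(0, 1 - z^2))
  th <- phi0 + i * golden
  pos <- cbind(r * cos(th), r * sin(th), z)
  pos <- pos / sqrt(rowSums(pos^2))
  montage(sprintf("E%03d", seq_len(n_channels)), pos)
}

#' Generate smooth, mutually separated template topographies
#'
#' Each template is the scalp potential of a few randomly placed
#' dipole-like sources inside the head sphere, average-referenced and
#' normalized to unit GFP. Candidates are drawn until all pairwise absolute
#' spatial correlations are at most `min_separation`.
#'
#' @param mont a `montage`.
#' @param k number of templates.
#' @param seed RNG seed.
#' @param min_separation upper bound on pairwise `|spatial_correlation|`,
#'   in (-1, 1).
#' @param max_tries retry budget per template before giving up.
#' @return a channels-by-k matrix; each column is a zero-mean, unit-GFP map.
#' @export
make_templates <- function(mont, k, seed = 1L, min_separation = 0.7,
                           max_tries = 400L) {
  if (k < 1L) stop("k must be at least 1")
  if (min_separation <= -1 || min_separation >= 1) {
    stop("min_separation must lie in (-1, 1)")
  }
  pos <- mont$positions
  .with_seed(.sub_seed(seed, "templates"), {
    out <- matrix(NA_real_, mont$n_channels, k)
    for (j in seq_len(k)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        v <- .dipole_map(pos)
        if (j == 1L) { ok <- TRUE } else {
          cors <- vapply(seq_len(j - 1L), function(i) {
            abs(spatial_correlation(v, out[, i]))
          }, numeric(1))
          ok <- all(cors <= min_separation)
        }
        if (ok) { out[, j] <- v; break }
      }
      if (!ok) {
        stop(sprintf(
          "could not place template %d with |correlation| <= %g after %d tries",
          j, min_separation, max_tries))
      }
    }
    colnames(out) <- sprintf("map%d", seq_len(k))
    out
  })
}

# Potential of 1-3 random current dipoles inside the sphere, evaluated at the
# electrode positions (1/r^2 falloff along the moment direction), then
# average-referenced and GFP-normalized. Smooth over the scalp by construction.
.dipole_map <- function(pos) {
  nd <- sample(1:3, 1L)
  v <- numeric(nrow(pos))
  for (d in seq_len(nd)) {
    p <- stats::rnorm(3); p <- p / sqrt(sum(p^2)) * stats::runif(1, 0.2, 0.7)
    m <- stats::rnorm(3); m <- m / sqrt(sum(m^2))
    dv <- sweep(pos, 2L, p, "-")
    r <- sqrt(rowSums(dv^2))
    v <- v + (dv %*% m) / r^3
  }
  normalize_map(v)
}

#' Ground-truth microstate timeline
#'
#' Associates template maps with non-overlapping time windows and a peak
#' field strength per window. The default timeline mirrors the canonical
#' visual-word ERP sequence: a P1-like map at 100-150 ms, an N1-like map at
#' 150-300 ms, a P2-like map at 300-400 ms and an N400-like map at
#' 400-500 ms.
#'
#' @param templates channels-by-k matrix of template maps (zero-mean,
#'   unit GFP columns).
#' @param entries data.frame with columns `map_id`, `t_start_ms`, `t_end_ms`.
#' @param amplitude_uV peak GFP (microvolts) of each entry's envelope.
#' @return an object of class `gt_timeline`.
#' @export
gt_timeline <- function(templates,
                        entries = data.frame(
                          map_id = 1:4,
                          t_start_ms = c(100, 150, 300, 400),
                          t_end_ms = c(150, 300, 400, 500)),
                        amplitude_uV = 3) {
  entries <- as.data.frame(entries)
  stopifnot(all(c("map_id", "t_start_ms", "t_end_ms") %in% names(entries)))
  o <- order(entries$t_start_ms)
  entries <- entries[o, , drop = FALSE]
  if (any(entries$t_end_ms <= entries$t_start_ms)) {
    stop("timeline windows must have positive length")
  }
  if (nrow(entries) > 1L &&
      any(entries$t_start_ms[-1L] < entries$t_end_ms[-nrow(entries)])) {
    stop("timeline windows must not overlap")
  }
  if (any(entries$map_id > ncol(templates) | entries$map_id < 1L)) {
    stop("every timeline map_id needs a template column")
  }
  entries$amplitude_uV <- rep_len(amplitude_uV, nrow(entries))
  structure(list(entries = entries, templates = templates),
            class = "gt_timeline")
}

#' Default condition-effect multipliers
#'
#' GFP scale factors per (map, design cell) implementing the qualitative
#' effect pattern the generator is meant to plant: the N1-window map is
#' stronger for motor verbs; the P1-, P2- and N400-window maps are stronger
#' in L2; the P1-window map is strongest in the L2 non-motor cell.
#'
#' @param n1_motor multiplier of the N1 map in the motor cells.
#' @param l2 multiplier of the P1/P2/N400 maps in the L2 cells.
#' @param p1_nonmotor multiplier of the P1 map in the non-motor cells.
#' @param p1_l2_nonmotor extra multiplier of the P1 map in L2 non-motor.
#' @return a 4 x 4 matrix, rows = maps 1..4 (P1, N1, P2, N400), columns =
#'   cells `L1.motor`, `L1.non-motor`, `L2.motor`, `L2.non-motor`.
#' @export
default_multipliers <- function(n1_motor = 1.3, l2 = 1.3,
                                p1_nonmotor = 1.15, p1_l2_nonmotor = 1.1) {
  cells <- .cells()
  keys <- .cell_key(cells$language, cells$embodiment)
  m <- matrix(1, 4L, 4L, dimnames = list(sprintf("map%d", 1:4), keys))
  for (j in seq_len(4L)) {
    lang <- cells$language[j]; emb <- cells$embodiment[j]
    if (emb == "non-motor") m[1L, j] <- m[1L, j] * p1_nonmotor
    if (lang == "L2")       m[1L, j] <- m[1L, j] * l2
    if (lang == "L2" && emb == "non-motor") {
      m[1L, j] <- m[1L, j] * p1_l2_nonmotor
    }
    if (emb == "motor")     m[2L, j] <- m[2L, j] * n1_motor
    if (lang == "L2")       m[3L, j] <- m[3L, j] * l2
    if (lang == "L2")       m[4L, j] <- m[4L, j] * l2
  }
  m
}

#' Configuration of the synthetic 2 x 2 ERP study
#'
#' @param seed master RNG seed; every random draw in the generator derives
#'   from it.
#' @param n_subjects number of subjects (default 29, the study size the
#'   generator emulates).
#' @param n_channels montage size (default 128).
#' @param sfreq sampling rate in Hz (default 1024).
#' @param epoch_ms epoch limits in ms relative to stimulus onset.
#' @param effect_multipliers maps-by-cells matrix of GFP scale factors
#'   (see [default_multipliers()]); all entries must be positive.
#' @param subject_sd log-scale SD of the multiplicative subject effect.
#' @param rho target correlation of a subject's effect across the four
#'   design cells (default 0.5).
#' @param noise_sd additive white sensor-noise SD in microvolts.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_subjects = 29L, n_channels = 128L,
                         sfreq = 1024, epoch_ms = c(-100, 700),
                         effect_multipliers = default_multipliers(),
                         subject_sd = 0.2, rho = 0.5, noise_sd = 0.5) {
  if (n_subjects < 2L) stop("need at least 2 subjects")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (any(effect_multipliers <= 0)) stop("all effect multipliers must be > 0")
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 n_channels = as.integer(n_channels), sfreq = sfreq,
                 epoch_ms = epoch_ms, effect_multipliers = effect_multipliers,
                 subject_sd = subject_sd, rho = rho, noise_sd = noise_sd),
            class = "synth_config")
}

# Hann envelope: half-cosine ramps up to the peak at mid-window, zero at both
# window edges, so band-pass filtering sees no step discontinuity.
.envelope <- function(times_ms, t_start, t_end, peak) {
  inside <- times_ms >= t_start & times_ms < t_end
  env <- numeric(length(times_ms))
  u <- (times_ms[inside] - t_start) / (t_end - t_start)
  env[inside] <- peak * 0.5 * (1 - cos(2 * pi * u))
  env
}

#' Simulate one subject's evoked ERP in one design cell
#'
#' The signal is the sum over timeline entries of
#' `template x envelope x effect multiplier x subject effect`, plus additive
#' white sensor noise; the pre-stimulus interval carries noise only, and the
#' result is baseline-corrected over the pre-stimulus window.
#'
#' @param cfg a `synth_config`.
#' @param timeline a `gt_timeline`.
#' @param subject_id subject index (1-based).
#' @param language,embodiment design-cell labels.
#' @param subject_effect multiplicative subject effect for this cell
#'   (drawn by [simulate_dataset()]; defaults to 1).
#' @return an `evoked_erp`.
#' @export
simulate_subject_erp <- function(cfg, timeline, subject_id,
                                 language, embodiment, subject_effect = 1) {
  cell <- .cell_key(language, embodiment)
  if (!cell %in% colnames(cfg$effect_multipliers)) {
    stop("unknown design cell: ", cell)
  }
  if (any(!timeline$entries$map_id %in% seq_len(ncol(timeline$templates)))) {
    stop("timeline refers to a map_id without a template")
  }
  mult <- cfg$effect_multipliers
  if (any(!rownames(mult) %in% colnames(timeline$templates)) &&
      nrow(mult) < max(timeline$entries$map_id)) {
    stop("effect multipliers refer to an unknown map_id")
  }
  nch <- nrow(timeline$templates)
  n <- round((cfg$epoch_ms[2] - cfg$epoch_ms[1]) / 1000 * cfg$sfreq + 0.5)
  times <- cfg$epoch_ms[1] + (seq_len(n) - 1L) / cfg$sfreq * 1000
  sig <- matrix(0, nch, n)
  for (i in seq_len(nrow(timeline$entries))) {
    e <- timeline$entries[i, ]
    env <- .envelope(times, e$t_start_ms, e$t_end_ms, e$amplitude_uV)
    sig <- sig + tcrossprod(timeline$templates[, e$map_id],
                            env * mult[e$map_id, cell] * subject_effect)
  }
  noise <- .with_seed(
    .sub_seed(cfg$seed, "noise", subject_id, cell),
    matrix(stats::rnorm(nch * n, sd = cfg$noise_sd), nch, n))
  x <- sig + noise
  bl <- times >= cfg$epoch_ms[1] & times < 0
  if (any(bl)) x <- x - rowMeans(x[, bl, drop = FALSE])
  evoked_erp(x, cfg$sfreq, cfg$epoch_ms[1],
             subject_id = sprintf("S%03d", subject_id),
             language = language, embodiment = embodiment,
             channel_names = sprintf("E%03d", seq_len(nch)))
}

#' Simulate a complete crossed 2 x 2 ERP dataset
#'
#' Generates montage, templates, per-subject multiplicative effects with
#' the configured between-cell correlation (log-normal marginals through a
#' Gaussian copula), and one evoked ERP per subject x design cell. The
#' ground truth is returned alongside the data.
#'
#' @param cfg a `synth_config`.
#' @param timeline optional `gt_timeline`; by default templates are drawn
#'   from the config seed and laid out on the default P1/N1/P2/N400 windows.
#' @return an object of class `erp_dataset`: a list with `erps` (list of
#'   `evoked_erp`, one per subject x cell), `montage`, `timeline`,
#'   `subject_effects` (subjects x cells) and `config`.
#' @export
simulate_dataset <- function(cfg, timeline = NULL) {
  mont <- make_montage(cfg$n_channels, seed = cfg$seed)
  if (is.null(timeline)) {
    tmpl <- make_templates(mont, k = 4L, seed = cfg$seed, min_separation = 0.5)
    timeline <- gt_timeline(tmpl)
  }
  cells <- .cells()
  keys <- .cell_key(cells$language, cells$embodiment)
  # Gaussian copula with equicorrelation rho across the four cells
  eff <- .with_seed(.sub_seed(cfg$seed, "subjects"), {
    z0 <- stats::rnorm(cfg$n_subjects)
    z <- sapply(seq_len(4L), function(j) {
      sqrt(cfg$rho) * z0 + sqrt(1 - cfg$rho) * stats::rnorm(cfg$n_subjects)
    })
    exp(cfg$subject_sd * z - cfg$subject_sd^2 / 2)
  })
  dimnames(eff) <- list(sprintf("S%03d", seq_len(cfg$n_subjects)), keys)
  erps <- vector("list", cfg$n_subjects * 4L)
  idx <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    for (j in seq_len(4L)) {
      idx <- idx + 1L
      erps[[idx]] <- simulate_subject_erp(
        cfg, timeline, s, cells$language[j], cells$embodiment[j],
        subject_effect = eff[s, j])
    }
  }
  structure(list(erps = erps, montage = mont, timeline = timeline,
                 subject_effects = eff, config = cfg),
            class = "erp_dataset")
}

#' @export
print.erp_dataset <- function(x, ...) {
  cat(sprintf(
    "<erp_dataset> %d subjects x 4 cells = %d evoked ERPs (%d ch @ %g Hz)\n",
    x$config$n_subjects, length(x$erps), x$config$n_channels, x$config$sfreq))
  invisible(x)
}
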