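#' Back-fitting and condition statistics
#'
#' Winner-take-all assignment of the group-level template maps to
#' single-subject condition ERPs, per-map summary measures (GEV, mean GFP,
#' duration), the 2 x 2 repeated-measures ANOVA with effect sizes, and the
#' within-factors power calculator.
#'
#' @name backfit_stats
NULL

#' Back-fit template maps to a single-subject ERP
#'
#' Each in-window sample is labeled with the template of maximal signed
#' spatial correlation (winner-take-all; ties break toward the lower map
#' index). Per map, the global explained variance, the mean GFP over the
#' samples the map wins, and the total duration in ms are extracted.
#' Zero-GFP samples are skipped. Maps that never win a sample get
#' GEV = 0, duration = 0 and mean GFP = 0.
#'
#' @param erp an `evoked_erp` (average-referenced internally).
#' @param templates channels-by-k template matrix.
#' @param analysis_window_ms half-open analysis window in ms.
#' @return list with `labels` (per in-window sample), `time_ms`, and
#'   `records`: a data.frame with one row per map
#'   (subject_id, language, embodiment, map_id, gev, mean_gfp, duration_ms).
#' @export
backfit_subject <- function(erp, templates,
                            analysis_window_ms = c(0, 700)) {
  stopifnot(inherits(erp, "evoked_erp"))
  erp <- average_reference(erp)
  tms <- erp_times(erp)
  sel <- tms >= analysis_window_ms[1] & tms < analysis_window_ms[2]
  if (!any(sel)) stop("empty analysis window")
  X <- erp$data[, sel, drop = FALSE]
  nz <- .normalize_columns(X)
  tn <- apply(as.matrix(templates), 2L, normalize_map)
  k <- ncol(tn)
  cc <- crossprod(nz$maps, tn) / nrow(X)          # samples x k correlations
  labels <- rep(NA_integer_, ncol(X))
  okc <- nz$ok
  if (any(okc)) {
    labels[okc] <- max.col(cc[okc, , drop = FALSE], ties.method = "first")
  }
  gev <- compute_gev(X, tn, labels)
  dt_ms <- 1000 / erp$sfreq
  recs <- data.frame(
    subject_id = erp$subject_id, language = erp$language,
    embodiment = erp$embodiment, map_id = seq_len(k),
    gev = gev$per_map,
    mean_gfp = vapply(seq_len(k), function(m) {
      s <- which(!is.na(labels) & labels == m)
      if (length(s)) mean(nz$gfp[s]) else 0
    }, numeric(1)),
    duration_ms = vapply(seq_len(k), function(m) {
      sum(!is.na(labels) & labels == m) * dt_ms
    }, numeric(1)),
    stringsAsFactors = FALSE)
  list(labels = labels, time_ms = tms[sel], records = recs)
}

#' Back-fit a segmentation to new ERP data
#'
#' `predict()` on a fitted segmentation performs winner-take-all
#' back-fitting of its templates to one or more evoked ERPs.
#'
#' @param object a `microstate_segmentation`.
#' @param newdata an `evoked_erp` or a list of them.
#' @param ... unused.
#' @return for a single ERP, the [backfit_subject()] result; for a list, a
#'   combined data.frame of back-fit records.
#' @export
predict.microstate_segmentation <- function(object, newdata, ...) {
  win <- object$params$analysis_window_ms
  if (inherits(newdata, "evoked_erp")) {
    return(backfit_subject(newdata, object$templates, win))
  }
  do.call(rbind, lapply(newdata, function(e) {
    backfit_subject(e, object$templates, win)$records
  }))
}

#' Two-by-two repeated-measures ANOVA
#'
#' Classical within-subject decomposition for a complete balanced 2 x 2
#' design with one observation per subject and cell: sums of squares for
#' subjects, the two main effects, their interaction, and the three
#' effect-by-subject error strata. Each effect is tested against its own
#' error stratum, `F = MS_effect / MS_{effect x subject}` with df (1, n-1).
#' Both partial eta squared (`SS_eff / (SS_eff + SS_err)`) and generalized
#' eta squared (`SS_eff / (SS_eff + all subject-related SS)`) are reported.
#'
#' @param data data.frame with one row per subject x cell.
#' @param value name of the response column.
#' @param subject,factor_a,factor_b names of the subject and the two
#'   (2-level) within-subject factor columns.
#' @return an object of class `rm_anova_2x2`: a data.frame with rows for
#'   the two main effects and the interaction (effect, F, df1, df2, p,
#'   eta2_partial, eta2_generalized), with the full SS decomposition in
#'   `attr(, "ss")`.
#' @export
rm_anova_2x2 <- function(data, value = "value", subject = "subject_id",
                         factor_a = "language", factor_b = "embodiment") {
  y <- data[[value]]
  s <- factor(data[[subject]])
  a <- factor(data[[factor_a]])
  b <- factor(data[[factor_b]])
  if (nlevels(a) != 2L || nlevels(b) != 2L) {
    stop("both factors must have exactly 2 levels")
  }
  n <- nlevels(s)
  if (n < 3L) stop("need at least 3 subjects")
  counts <- table(s, a, b)
  if (any(counts != 1L)) {
    bad <- which(counts != 1L, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "incomplete or unbalanced design: subject %s has %d value(s) in cell %s/%s",
      dimnames(counts)[[1L]][bad[1L]],
      counts[bad[1L], bad[2L], bad[3L]],
      dimnames(counts)[[2L]][bad[2L]], dimnames(counts)[[3L]][bad[3L]]))
  }
  gm <- mean(y)
  m_a <- tapply(y, a, mean); m_b <- tapply(y, b, mean)
  m_s <- tapply(y, s, mean)
  m_ab <- tapply(y, list(a, b), mean)
  m_sa <- tapply(y, list(s, a), mean)
  m_sb <- tapply(y, list(s, b), mean)
  ss_a <- 2 * n * sum((m_a - gm)^2)
  ss_b <- 2 * n * sum((m_b - gm)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1L, m_a, "-"), 2L, m_b, "-") + gm)^2)
  ss_s <- 4 * sum((m_s - gm)^2)
  ss_as <- 2 * sum((m_sa - outer(m_s, rep(1, 2)) -
                      outer(rep(1, n), m_a) + gm)^2)
  ss_bs <- 2 * sum((m_sb - outer(m_s, rep(1, 2)) -
                      outer(rep(1, n), m_b) + gm)^2)
  fitted3 <- m_sa[cbind(as.integer(s), as.integer(a))] +
    m_sb[cbind(as.integer(s), as.integer(b))] +
    m_ab[cbind(as.integer(a), as.integer(b))] -
    m_s[as.integer(s)] - m_a[as.integer(a)] - m_b[as.integer(b)] + gm
  ss_abs <- sum((y - fitted3)^2)
  subj_related <- ss_s + ss_as + ss_bs + ss_abs
  mk_row <- function(eff, ss_eff, ss_err) {
    ms_eff <- ss_eff / 1
    ms_err <- ss_err / (n - 1L)
    if (ms_err <= .Machine$double.eps * max(1, ms_eff)) {
      if (ss_eff > 0) {
        warning(sprintf("zero error variance for effect '%s': F degenerate",
                        eff))
        Fv <- Inf; p <- 0
      } else { Fv <- NaN; p <- 1 }
    } else {
      Fv <- ms_eff / ms_err
      p <- stats::pf(Fv, 1, n - 1L, lower.tail = FALSE)
    }
    data.frame(effect = eff, F = Fv, df1 = 1L, df2 = n - 1L, p = p,
               eta2_partial = if (ss_eff + ss_err > 0)
                 ss_eff / (ss_eff + ss_err) else 0,
               eta2_generalized = if (ss_eff + subj_related > 0)
                 ss_eff / (ss_eff + subj_related) else 0,
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk_row(factor_a, ss_a, ss_as),
               mk_row(factor_b, ss_b, ss_bs),
               mk_row("interaction", ss_ab, ss_abs))
  attr(out, "ss") <- c(subject = ss_s, A = ss_a, B = ss_b, AB = ss_ab,
                       A_x_subject = ss_as, B_x_subject = ss_bs,
                       AB_x_subject = ss_abs)
  attr(out, "n_subjects") <- n
  class(out) <- c("rm_anova_2x2", "data.frame")
  out
}

#' @export
print.rm_anova_2x2 <- function(x, ...) {
  cat(sprintf("2 x 2 repeated-measures ANOVA (n = %d)\n",
              attr(x, "n_subjects")))
  df <- as.data.frame(x)
  df$F <- signif(df$F, 5); df$p <- signif(df$p, 4)
  df$eta2_partial <- signif(df$eta2_partial, 3)
  df$eta2_generalized <- signif(df$eta2_generalized, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Power of a within-factors repeated-measures ANOVA
#'
#' Power at sample size `n` for a one-group repeated-measures design with
#' `m` measurements, computed from the noncentral F distribution with
#' noncentrality `lambda = f^2 * n * m * epsilon / (1 - rho)` and degrees
#' of freedom `df1 = (m - 1) * epsilon`,
#' `df2 = (n - n_groups) * (m - 1) * epsilon`.
#'
#' @param n total sample size.
#' @param alpha type-I error level.
#' @param f Cohen's effect size f.
#' @param rho correlation among the repeated measures.
#' @param epsilon nonsphericity correction in (0, 1].
#' @param n_groups number of groups (1 for a pure within design).
#' @param n_measurements number of repeated measurements m.
#' @return the power, a scalar in (0, 1).
#' @export
rm_anova_power <- function(n, alpha = 0.05, f = 0.25, rho = 0.5,
                           epsilon = 1, n_groups = 1L, n_measurements = 4L) {
  m <- n_measurements
  lambda <- f^2 * n * m * epsilon / (1 - rho)
  df1 <- (m - 1) * epsilon
  df2 <- (n - n_groups) * (m - 1) * epsilon
  if (df2 < 1) return(NA_real_)
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Minimal sample size for a target power
#'
#' Scans integer total sample sizes upward and returns the smallest `n`
#' whose power (see [rm_anova_power()]) meets or exceeds the target.
#'
#' @param alpha type-I error level (0 < alpha < 1).
#' @param f Cohen's effect size f (> 0).
#' @param power_target target power (0 < target < 1).
#' @param rho correlation among repeated measures, in [0, 1).
#' @param epsilon nonsphericity in (0, 1].
#' @param n_groups number of groups.
#' @param n_measurements number of repeated measurements.
#' @param n_cap search cap; exceeding it is an error.
#' @return list with `n` (minimal total sample size) and `power` (achieved
#'   power at that n).
#' @export
rm_anova_power_n <- function(alpha = 0.05, f = 0.25, power_target = 0.8,
                             rho = 0.5, epsilon = 1, n_groups = 1L,
                             n_measurements = 4L, n_cap = 10000L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (f <= 0) stop("f must be positive")
  if (power_target <= 0 || power_target >= 1) {
    stop("power_target must lie in (0, 1)")
  }
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (epsilon <= 0 || epsilon > 1) stop("epsilon must lie in (0, 1]")
  for (n in seq.int(max(3L, n_groups + 1L), n_cap)) {
    pw <- rm_anova_power(n, alpha, f, rho, epsilon, n_groups, n_measurements)
    if (!is.na(pw) && pw >= power_target) {
      return(list(n = n, power = pw))
    }
  }
  stop(sprintf("no n <= %d reaches power %g", n_cap, power_target))
}

#' Run the full microstate analysis pipeline
#'
#' Average-references every evoked response, builds the four condition
#' grand averages, segments them into microstate maps, back-fits the
#' templates to every subject x cell ERP, and runs the 2 x 2
#' repeated-measures ANOVA per map and measure (GEV, mean GFP, duration).
#'
#' @param dataset an `erp_dataset` from [simulate_dataset()], or a plain
#'   list of `evoked_erp` covering a complete 2 x 2 design.
#' @param params a `segmentation_params`.
#' @param k_fixed optionally fix the number of maps (bypassing criterion
#'   selection).
#' @return an object of class `microstate_analysis`: `segmentation`
#'   (a `microstate_segmentation`), `backfit` (data.frame of per
#'   subject x cell x map records), `anova` (data.frame with one row per
#'   map x measure x effect), `grand_averages`.
#' @export
run_full_analysis <- function(dataset, params = segmentation_params(),
                              k_fixed = NULL) {
  erps <- if (inherits(dataset, "erp_dataset")) dataset$erps else dataset
  if (!all(vapply(erps, inherits, logical(1), "evoked_erp"))) {
    stop("analysis stage: dataset must contain evoked_erp objects")
  }
  erps <- lapply(erps, average_reference)
  cells <- .cells()
  gas <- lapply(seq_len(4L), function(j) {
    sel <- vapply(erps, function(e) {
      e$language == cells$language[j] && e$embodiment == cells$embodiment[j]
    }, logical(1))
    if (!any(sel)) {
      stop(sprintf("analysis stage: no ERPs for cell %s/%s",
                   cells$language[j], cells$embodiment[j]))
    }
    grand_average(erps[sel])
  })
  seg <- segment_microstates(gas, params, k_fixed = k_fixed)
  bf <- do.call(rbind, lapply(erps, function(e) {
    backfit_subject(e, seg$templates, params$analysis_window_ms)$records
  }))
  rownames(bf) <- NULL
  measures <- c(gev = "gev", mean_gfp = "mean_gfp",
                duration_ms = "duration_ms")
  an <- do.call(rbind, lapply(seq_len(seg$selected_k), function(m) {
    sub <- bf[bf$map_id == m, , drop = FALSE]
    do.call(rbind, lapply(names(measures), function(ms) {
      tab <- tryCatch(
        suppressWarnings(rm_anova_2x2(sub, value = measures[[ms]])),
        error = function(e) NULL)
      if (is.null(tab)) return(NULL)
      cbind(data.frame(map_id = m, measure = ms), as.data.frame(tab))
    }))
  }))
  rownames(an) <- NULL
  structure(list(segmentation = seg, backfit = bf, anova = an,
                 grand_averages = gas, params = params),
            class = "microstate_analysis")
}

#' @export
print.microstate_analysis <- function(x, ...) {
  cat(sprintf(
    "<microstate_analysis> %d maps, %d back-fit records, %d ANOVA rows\n",
    x$segmentation$selected_k, nrow(x$backfit), nrow(x$anova)))
  sig <- x$anova[x$anova$p < 0.05, , drop = FALSE]
  if (nrow(sig)) {
    cat("significant effects (p < 0.05):\n")
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  map %d %s: %s F(%d,%d) = %.3f, p = %.4f\n",
                  sig$map_id[i], sig$measure[i], sig$effect[i],
                  sig$df1[i], sig$df2[i], sig$F[i], sig$p[i]))
    }
  }
  invisible(x)
}

#' @export
summary.microstate_analysis <- function(object, ...) {
  summary(object$segmentation)
  print(object)
  invisible(object)
}
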