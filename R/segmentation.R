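#' Spatio-temporal microstate segmentation
#'
#' Atomize-agglomerate hierarchical clustering (AAHC) of GFP-normalized
#' scalp topographies from the concatenated condition grand averages,
#' a k-sweep with multi-criterion selection of the number of maps, and a
#' minimum-duration temporal constraint.
#'
#' @name segmentation
NULL

#' Segmentation parameters
#'
#' @param k_max largest number of clusters recorded in the sweep
#'   (default 20).
#' @param min_segment_ms minimum microstate duration in ms; shorter runs
#'   are dissolved into their temporal neighbours (default 10).
#' @param analysis_window_ms post-stimulus interval submitted to clustering
#'   and back-fitting, in ms (half-open; default 0-700). The pre-stimulus
#'   baseline is excluded so that noise maps cannot pollute the templates.
#' @param criteria which k-selection criteria to combine; any subset of
#'   `"cv"` (cross-validation criterion), `"kl"` (Krzanowski-Lai index),
#'   `"dispersion"` (within-cluster dispersion ratio) and `"silhouette"`
#'   (mean silhouette on spatial-correlation distances).
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(k_max = 20L, min_segment_ms = 10,
                                analysis_window_ms = c(0, 700),
                                criteria = c("cv", "kl", "dispersion",
                                             "silhouette")) {
  if (k_max < 1L) stop("k_max must be >= 1")
  if (min_segment_ms < 0) stop("min_segment_ms must be >= 0")
  criteria <- match.arg(criteria,
                        c("cv", "kl", "dispersion", "silhouette"),
                        several.ok = TRUE)
  structure(list(k_max = as.integer(k_max), min_segment_ms = min_segment_ms,
                 analysis_window_ms = analysis_window_ms,
                 criteria = criteria),
            class = "segmentation_params")
}

# Assemble the concatenated clustering frame from the condition grand
# averages: average-referenced in-window maps, their GFP, normalized copies,
# and bookkeeping (condition of origin, time in ms, zero-GFP exclusions).
.clustering_frame <- function(grand_averages, window_ms) {
  stopifnot(length(grand_averages) >= 1L)
  maps <- list(); gfps <- list(); cond <- list(); tms <- list()
  for (ci in seq_along(grand_averages)) {
    ga <- average_reference(grand_averages[[ci]])
    t_all <- erp_times(ga)
    sel <- t_all >= window_ms[1] & t_all < window_ms[2]
    if (!any(sel)) stop("empty analysis window")
    maps[[ci]] <- ga$data[, sel, drop = FALSE]
    cond[[ci]] <- rep(ci, sum(sel))
    tms[[ci]] <- t_all[sel]
  }
  X <- do.call(cbind, maps)
  nz <- .normalize_columns(X)
  n_excluded <- sum(!nz$ok)
  if (n_excluded > 0L) {
    message(sprintf("%d zero-GFP timepoint(s) excluded from clustering",
                    n_excluded))
  }
  list(X = X, Vn = nz$maps, gfp = nz$gfp, ok = nz$ok,
       condition = unlist(cond), time_ms = unlist(tms),
       sfreq = grand_averages[[1L]]$sfreq,
       cond_names = vapply(grand_averages, function(g) {
         paste(g$language, g$embodiment, sep = ".")
       }, character(1)))
}

#' AAHC clustering of grand-average topographies
#'
#' Every (GFP-normalized, average-referenced) in-window timepoint map of the
#' concatenated condition grand averages starts as its own cluster. The
#' cluster contributing least global explained variance (GEV) is atomized;
#' each freed map is reassigned to the cluster whose centroid it correlates
#' with best (signed spatial correlation), centroids are recomputed as the
#' GFP-normalized mean of member maps, and a solution is recorded every time
#' the cluster count reaches `k <= k_max`.
#'
#' @param grand_averages list of condition `evoked_erp` grand averages
#'   sharing montage and sampling rate (typically the four design cells).
#' @param params a `segmentation_params`.
#' @return a list of class `aahc_sweep`: `solutions` (one per k = 1..k_max;
#'   each with `k`, `templates` channels-by-k, `labels` over concatenated
#'   in-window samples with NA at zero-GFP exclusions, `gev_per_map`,
#'   `gev_total`), plus the clustering `frame`.
#' @export
aahc_cluster <- function(grand_averages, params = segmentation_params()) {
  fr <- .clustering_frame(grand_averages, params$analysis_window_ms)
  keep <- which(fr$ok)
  if (length(keep) < 1L) stop("no non-degenerate timepoints to cluster")
  Vn <- fr$Vn[, keep, drop = FALSE]
  X <- fr$X[, keep, drop = FALSE]
  X <- sweep(X, 2L, colMeans(X), "-")
  g2 <- fr$gfp[keep]^2
  nch <- nrow(Vn)
  Tn <- ncol(Vn)
  k_max <- min(params$k_max, Tn)

  assign <- seq_len(Tn)
  live <- rep(TRUE, Tn)
  centroids <- Vn                       # column i: centroid of cluster i
  contrib <- g2                         # per-cluster GEV numerator
  tot_g2 <- sum(g2)
  solutions <- vector("list", k_max)

  # Stabilize a recorded solution: alternate winner-take-all reassignment
  # (signed correlation, ties to the lower cluster index) and centroid
  # updates until the labeling is stationary. The greedy atomization
  # sequence alone can stay measurably short of the attainable explained
  # variance; the stabilized state also seeds the next atomization.
  refine <- function() {
    ids <- which(live)
    for (it in seq_len(100L)) {
      cc <- crossprod(Vn, centroids[, ids, drop = FALSE]) / nch
      new_assign <- ids[max.col(cc, ties.method = "first")]
      if (all(new_assign == assign)) break
      changed <- unique(c(assign[new_assign != assign],
                          new_assign[new_assign != assign]))
      assign <<- new_assign
      for (a in changed) .update_cluster(a)
    }
  }

  record <- function(K) {
    refine()
    ids <- which(live)
    lab_full <- rep(NA_integer_, length(fr$ok))
    lab_full[keep] <- match(assign, ids)
    tpl <- centroids[, ids, drop = FALSE]
    colnames(tpl) <- sprintf("map%d", seq_len(K))
    per_map <- as.numeric(contrib[ids]) / tot_g2
    solutions[[K]] <<- list(k = K, templates = tpl, labels = lab_full,
                            gev_per_map = per_map,
                            gev_total = sum(per_map))
  }

  # centroid = GFP-normalized arithmetic mean of the member maps; averaging
  # the original (strength-carrying) maps lets high-GFP members dominate,
  # consistent with the GFP^2-weighted GEV objective
  .update_cluster <- function(a) {
    mem <- which(assign == a)
    if (length(mem) == 0L) { contrib[a] <<- 0; return(invisible()) }
    cen <- rowMeans(X[, mem, drop = FALSE])
    cen <- cen - mean(cen)
    g <- sqrt(mean(cen^2))
    if (g <= .tol_zero_gfp) {
      # members cancel exactly; keep the strongest member's map as centroid
      cen <- Vn[, mem[which.max(g2[mem])]]
    } else {
      cen <- cen / g
    }
    centroids[, a] <<- cen
    cc <- crossprod(Vn[, mem, drop = FALSE], cen) / nch
    contrib[a] <<- sum(g2[mem] * cc^2)
  }

  # Worst-cluster rule: while many clusters remain, the cluster with the
  # smallest current GEV contribution. Near the recorded range, switch to
  # the marginal-loss form -- the cluster whose atomization costs the least
  # explained variance once its members are recovered by the remaining
  # centroids. The marginal form dissolves redundant near-duplicate
  # centroids first instead of sacrificing genuine low-power maps.
  marginal_thr <- max(k_max + 10L, 30L)
  .worst_cluster <- function(ids) {
    if (length(ids) > marginal_thr) {
      return(ids[which.min(contrib[ids])])
    }
    CC <- crossprod(Vn, centroids[, ids, drop = FALSE]) / nch
    loss <- vapply(seq_along(ids), function(j) {
      mem <- which(assign == ids[j])
      own <- CC[mem, j]
      other <- apply(CC[mem, -j, drop = FALSE], 1L, max)
      sum(g2[mem] * (own^2 - other^2))
    }, numeric(1))
    ids[which.min(loss)]
  }

  K <- Tn
  if (K <= k_max) record(K)
  while (K > 1L) {
    ids <- which(live)
    w <- if (K == 2L) ids[which.min(contrib[ids])] else .worst_cluster(ids)
    members <- which(assign == w)
    live[w] <- FALSE
    K <- K - 1L
    others <- which(live)
    cc <- crossprod(Vn[, members, drop = FALSE],
                    centroids[, others, drop = FALSE]) / nch
    assign[members] <- others[max.col(cc, ties.method = "first")]
    for (a in unique(assign[members])) .update_cluster(a)
    if (K <= k_max) record(K)
  }
  structure(list(solutions = solutions, frame = fr, k_max = k_max),
            class = "aahc_sweep")
}

#' Global explained variance of a labeling
#'
#' For template maps `T_m` and per-sample labels, the per-map GEV is
#' `GEV_m = sum_{t: label(t)=m} (GFP_t * C(u_t, T_m))^2 / sum_t GFP_t^2`,
#' with `C` the signed spatial correlation; the denominator runs over all
#' (non-degenerate) samples in scope, so unlabeled samples lower the total.
#'
#' @param x channels-by-samples matrix or `evoked_erp` (average-referenced
#'   internally).
#' @param templates channels-by-k template matrix.
#' @param labels integer vector (length = samples) of template indices,
#'   NA = unlabeled.
#' @return list with `per_map` (length k) and `total`, all in `[0, 1]`.
#' @export
compute_gev <- function(x, templates, labels) {
  if (inherits(x, "evoked_erp")) x <- x$data
  x <- average_reference(as.matrix(x))
  templates <- as.matrix(templates)
  if (length(labels) != ncol(x)) stop("labels must align with data samples")
  nz <- .normalize_columns(x)
  g2 <- nz$gfp^2
  tot <- sum(g2[nz$ok])
  if (tot <= .tol_zero_gfp^2) stop("zero total GFP: GEV undefined")
  k <- ncol(templates)
  tn <- apply(templates, 2L, normalize_map)
  per_map <- numeric(k)
  for (m in seq_len(k)) {
    sel <- which(!is.na(labels) & labels == m & nz$ok)
    if (length(sel) == 0L) next
    cc <- crossprod(nz$maps[, sel, drop = FALSE], tn[, m]) / nrow(x)
    per_map[m] <- sum(g2[sel] * cc^2) / tot
  }
  list(per_map = per_map, total = sum(per_map))
}

# run-length segments of a label vector within one condition, treating NA as
# boundaries; returns data.frame(start, end, len, map)
.label_runs <- function(lab) {
  n <- length(lab)
  r <- rle(ifelse(is.na(lab), -1L, lab))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts, end = ends, len = r$lengths, map = r$values)
}

#' Enforce a minimum microstate duration
#'
#' Label runs shorter than `min_segment_ms` are dissolved: each sample of a
#' short run is reassigned to whichever flanking run's map it correlates
#' with best (signed spatial correlation), iterating shortest-run-first
#' until no short run remains or a safety cap is hit; remaining stragglers
#' are then merged wholesale into their better-correlated flank. Runs at or
#' above the threshold are never touched. If a condition's labeling is
#' degenerate (no run can survive), all its samples fall back to the single
#' map with the largest total GEV, with a warning.
#'
#' @param labels integer label vector over concatenated samples (NA allowed).
#' @param min_segment_ms minimum duration in ms; 0 disables smoothing.
#' @param sfreq sampling rate in Hz.
#' @param x channels-by-samples matrix of (average-referenced) maps aligned
#'   with `labels`.
#' @param templates channels-by-k template matrix.
#' @param condition optional integer vector marking each sample's condition;
#'   runs never extend across condition boundaries.
#' @return smoothed integer label vector.
#' @export
apply_temporal_constraint <- function(labels, min_segment_ms, sfreq,
                                      x, templates,
                                      condition = NULL) {
  if (min_segment_ms <= 0) return(labels)
  if (inherits(x, "evoked_erp")) x <- x$data
  x <- as.matrix(x)
  if (is.null(condition)) condition <- rep(1L, length(labels))
  nz <- .normalize_columns(average_reference(x))
  tn <- apply(as.matrix(templates), 2L, normalize_map)
  nch <- nrow(x)
  min_len <- function(s) s / sfreq * 1000 >= min_segment_ms
  corr_with <- function(i, m) {
    if (!nz$ok[i]) return(-Inf)
    sum(nz$maps[, i] * tn[, m]) / nch
  }
  out <- labels
  for (ci in unique(condition)) {
    idx <- which(condition == ci)
    lab <- out[idx]
    for (pass in seq_len(200L)) {
      runs <- .label_runs(lab)
      runs <- runs[runs$map > 0L, , drop = FALSE]
      short <- runs[!min_len(runs$len), , drop = FALSE]
      if (nrow(short) == 0L) break
      if (nrow(short) == nrow(runs)) {
        # degenerate: nothing long enough to absorb into
        gtot <- vapply(seq_len(ncol(tn)), function(m) {
          compute_gev(x[, idx, drop = FALSE], templates,
                      rep(m, length(idx)))$total
        }, numeric(1))
        best <- which.max(gtot)
        warning("all runs below the minimum duration; falling back to the ",
                "single globally best map")
        lab[!is.na(lab)] <- best
        break
      }
      # dissolve the shortest (earliest on ties) short run
      o <- order(short$len, short$start)
      r <- short[o[1L], ]
      all_runs <- .label_runs(lab)
      pos <- which(all_runs$start == r$start)
      lmap <- if (pos > 1L && all_runs$map[pos - 1L] > 0L)
        all_runs$map[pos - 1L] else NA_integer_
      rmap <- if (pos < nrow(all_runs) && all_runs$map[pos + 1L] > 0L)
        all_runs$map[pos + 1L] else NA_integer_
      cand <- unique(stats::na.omit(c(lmap, rmap)))
      if (length(cand) == 0L) { lab[r$start:r$end] <- NA_integer_; next }
      for (i in r$start:r$end) {
        if (is.na(lab[i])) next
        cs <- vapply(cand, function(m) corr_with(idx[i], m), numeric(1))
        lab[i] <- cand[which.max(cs)]   # ties -> lower map id (first)
      }
    }
    # safety cleanup: merge any remaining short run wholesale
    runs <- .label_runs(lab)
    runs <- runs[runs$map > 0L, , drop = FALSE]
    guard <- 0L
    while (nrow(runs) > 1L && any(!min_len(runs$len)) && guard < 1000L) {
      guard <- guard + 1L
      all_runs <- .label_runs(lab)
      kpos <- which(all_runs$map > 0L & !min_len(all_runs$len))[1L]
      r <- all_runs[kpos, ]
      lmap <- if (kpos > 1L && all_runs$map[kpos - 1L] > 0L)
        all_runs$map[kpos - 1L] else NA_integer_
      rmap <- if (kpos < nrow(all_runs) && all_runs$map[kpos + 1L] > 0L)
        all_runs$map[kpos + 1L] else NA_integer_
      cand <- unique(stats::na.omit(c(lmap, rmap)))
      if (length(cand) == 0L) break
      mc <- vapply(cand, function(m) {
        mean(vapply(r$start:r$end, function(i) corr_with(idx[i], m),
                    numeric(1)))
      }, numeric(1))
      lab[r$start:r$end][!is.na(lab[r$start:r$end])] <- cand[which.max(mc)]
      runs <- .label_runs(lab)
      runs <- runs[runs$map > 0L, , drop = FALSE]
    }
    out[idx] <- lab
  }
  out
}

# ---- k-selection criteria -------------------------------------------------

# Within-cluster dispersion: sum over samples of the squared residual of the
# (unnormalized, average-referenced) map after projection on its cluster's
# unit-norm centroid.
.dispersion_w <- function(X, sol) {
  lab <- sol$labels
  W <- 0
  for (m in seq_len(sol$k)) {
    sel <- which(!is.na(lab) & lab == m)
    if (length(sel) == 0L) next
    c_unit <- sol$templates[, m] / sqrt(sum(sol$templates[, m]^2))
    xm <- X[, sel, drop = FALSE]
    proj <- crossprod(xm, c_unit)
    W <- W + sum(xm^2) - sum(proj^2)
  }
  W
}

#' Select the number of microstate maps by criterion convergence
#'
#' Computes each enabled criterion for every k in the sweep; each criterion
#' casts a vote for its preferred k (CV: minimum; Krzanowski-Lai: maximum;
#' dispersion ratio: smallest k whose Hartigan-style statistic
#' `(W_k/W_{k+1} - 1)(T - k - 1)` falls below 10; silhouette: smallest k
#' within the index resolution, 0.02, of the maximum). A candidate k is
#' ranked per criterion by its distance to that criterion's vote, and the k
#' with the best median rank wins, ties breaking toward smaller k -- the
#' point of convergence of the criteria. The criteria trade explained
#' variance against parsimony, so unstructured data select small k.
#'
#' @param sweep an `aahc_sweep` from [aahc_cluster()].
#' @param criteria criterion subset (see [segmentation_params()]).
#' @param k_candidates integer vector of ks to consider (default: 2 up to
#'   the sweep's k_max; k = 1 offers no contrast for any criterion).
#' @return list with `selected_k`, `criterion_scores` (k x criterion
#'   matrix), and `ranks`.
#' @export
meta_criterion_select <- function(sweep,
                                  criteria = c("cv", "kl", "dispersion",
                                               "silhouette"),
                                  k_candidates = NULL) {
  sols <- sweep$solutions
  ks_all <- which(!vapply(sols, is.null, logical(1)))
  if (length(ks_all) < 2L) {
    warning("single-k sweep: returning the only available solution")
    return(list(selected_k = ks_all, criterion_scores = NULL, ranks = NULL))
  }
  if (is.null(k_candidates)) k_candidates <- ks_all[ks_all >= 2L]
  k_candidates <- sort(intersect(k_candidates, ks_all))
  X <- sweep$frame$X[, sweep$frame$ok, drop = FALSE]
  nch <- nrow(X)
  Tn <- ncol(X)
  kw <- seq(min(ks_all), max(ks_all))
  Wk <- rep(NA_real_, max(ks_all))
  for (k in kw) {
    Wk[k] <- .dispersion_w(X, .restrict_solution(sols[[k]], sweep$frame$ok))
  }
  scores <- matrix(NA_real_, length(k_candidates), length(criteria),
                   dimnames = list(as.character(k_candidates), criteria))
  lower_better <- c(cv = TRUE, kl = FALSE, dispersion = FALSE,
                    silhouette = FALSE)
  if ("silhouette" %in% criteria) {
    sub <- if (Tn > 1200L) {
      as.integer(seq(1L, Tn, length.out = 1200L))
    } else seq_len(Tn)
    D <- 1 - crossprod(sweep$frame$Vn[, sweep$frame$ok][, sub, drop = FALSE]) /
      nch
  }
  for (i in seq_along(k_candidates)) {
    k <- k_candidates[i]
    sol <- .restrict_solution(sols[[k]], sweep$frame$ok)
    if ("cv" %in% criteria) {
      scores[i, "cv"] <- if (k >= nch - 1L) Inf else {
        (Wk[k] / (Tn * (nch - 1L))) * ((nch - 1L) / (nch - 1L - k))^2
      }
    }
    if ("kl" %in% criteria) {
      if (k - 1L >= min(ks_all) && k + 1L <= max(ks_all)) {
        diffk <- (k - 1)^(2 / nch) * Wk[k - 1L] - k^(2 / nch) * Wk[k]
        diffk1 <- k^(2 / nch) * Wk[k] - (k + 1)^(2 / nch) * Wk[k + 1L]
        scores[i, "kl"] <- abs(diffk) / max(abs(diffk1), 1e-12)
      }
    }
    if ("dispersion" %in% criteria) {
      if (k + 1L <= max(ks_all) && Wk[k + 1L] > 0) {
        scores[i, "dispersion"] <-
          (Wk[k] / Wk[k + 1L] - 1) * (Tn - k - 1L)
      }
    }
    if ("silhouette" %in% criteria) {
      scores[i, "silhouette"] <- .mean_silhouette(D, sol$labels[sub], k)
    }
  }
  # Each criterion casts a vote for its preferred k; a k's rank under a
  # criterion is its distance to that vote. The k with the best median rank
  # (ties toward smaller k) is the point of convergence of the criteria.
  votes <- vapply(criteria, function(cr) {
    s <- scores[, cr]
    switch(cr,
      cv = k_candidates[which.min(ifelse(is.na(s), Inf, s))],
      kl = k_candidates[which.max(ifelse(is.na(s), -Inf, s))],
      dispersion = {
        # Hartigan-style: smallest k for which adding one more cluster no
        # longer yields a substantial drop in dispersion
        h <- s
        cand <- k_candidates[!is.na(h) & h < 10]
        if (length(cand)) min(cand) else max(k_candidates)
      },
      silhouette = {
        # smallest k within the index resolution (0.02) of the maximum
        s2 <- ifelse(is.na(s), -Inf, s)
        min(k_candidates[s2 >= max(s2) - 0.02])
      })
  }, numeric(1))
  ranks <- vapply(criteria, function(cr) abs(k_candidates - votes[[cr]]),
                  numeric(length(k_candidates)))
  ranks <- matrix(ranks, nrow = length(k_candidates),
                  dimnames = list(as.character(k_candidates), criteria))
  med <- apply(ranks, 1L, stats::median)
  selected_k <- k_candidates[which.min(med)]   # ties -> smaller k
  list(selected_k = selected_k, criterion_scores = scores, ranks = ranks,
       votes = votes, median_rank = med)
}

# drop the NA (zero-GFP) positions from a solution's labels so they align
# with the kept columns of the clustering frame
.restrict_solution <- function(sol, ok) {
  sol$labels <- sol$labels[ok]
  sol
}

.mean_silhouette <- function(D, lab, k) {
  n <- length(lab)
  keep <- which(!is.na(lab))
  if (length(keep) < 3L) return(NA_real_)
  lab <- lab[keep]; D <- D[keep, keep, drop = FALSE]
  sizes <- tabulate(lab, nbins = k)
  if (sum(sizes > 0L) < 2L) return(NA_real_)
  sil <- numeric(length(lab))
  # mean distance from each point to each cluster, vectorized
  M <- matrix(0, length(lab), k)
  for (m in seq_len(k)) {
    if (sizes[m] == 0L) { M[, m] <- Inf; next }
    M[, m] <- rowSums(D[, lab == m, drop = FALSE]) / sizes[m]
  }
  for (i in seq_along(lab)) {
    m <- lab[i]
    a <- if (sizes[m] > 1L) M[i, m] * sizes[m] / (sizes[m] - 1L) else 0
    b <- min(M[i, -m])
    sil[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(sil)
}

#' Segment condition grand averages into microstates
#'
#' The central fitting function: runs the AAHC k-sweep on the concatenated
#' condition grand averages, selects the number of maps by criterion
#' convergence, applies the minimum-duration temporal constraint to the
#' selected solution, and derives per-condition map time windows.
#'
#' @param grand_averages list of condition grand-average `evoked_erp`s
#'   (typically the four cells of the 2 x 2 design).
#' @param params a `segmentation_params`.
#' @param k_fixed optionally bypass criterion selection and use this k.
#' @return an object of class `microstate_segmentation` with elements
#'   `templates` (channels x selected_k), `selected_k`, `labels`
#'   (per condition, integer vector over in-window samples), `time_ms`,
#'   `map_windows` (per condition data.frame of map occupancy windows),
#'   `gev` (before/after the temporal constraint), `solutions`,
#'   `criterion_scores`, `params`.
#' @export
segment_microstates <- function(grand_averages,
                                params = segmentation_params(),
                                k_fixed = NULL) {
  sweep <- aahc_cluster(grand_averages, params)
  if (is.null(k_fixed)) {
    sel <- meta_criterion_select(sweep, criteria = params$criteria)
    selected_k <- sel$selected_k
    criterion_scores <- sel$criterion_scores
  } else {
    if (is.null(sweep$solutions[[k_fixed]])) stop("k_fixed not in the sweep")
    selected_k <- as.integer(k_fixed)
    criterion_scores <- NULL
  }
  sol <- sweep$solutions[[selected_k]]
  fr <- sweep$frame
  gev_before <- compute_gev(fr$X, sol$templates, sol$labels)
  labels_sm <- apply_temporal_constraint(
    sol$labels, params$min_segment_ms, fr$sfreq,
    fr$X, sol$templates, condition = fr$condition)
  gev_after <- compute_gev(fr$X, sol$templates, labels_sm)
  conds <- unique(fr$condition)
  labels_by_cond <- lapply(conds, function(ci) labels_sm[fr$condition == ci])
  times_by_cond <- lapply(conds, function(ci) fr$time_ms[fr$condition == ci])
  names(labels_by_cond) <- names(times_by_cond) <- fr$cond_names[conds]
  map_windows <- lapply(seq_along(conds), function(j) {
    lab <- labels_by_cond[[j]]; tm <- times_by_cond[[j]]
    runs <- .label_runs(lab)
    runs <- runs[runs$map > 0L, , drop = FALSE]
    if (nrow(runs) == 0L) {
      return(data.frame(map_id = integer(), t_start_ms = numeric(),
                        t_end_ms = numeric()))
    }
    dt <- 1000 / fr$sfreq
    data.frame(map_id = runs$map,
               t_start_ms = tm[runs$start],
               t_end_ms = tm[runs$end] + dt)
  })
  names(map_windows) <- names(labels_by_cond)
  structure(list(templates = sol$templates, selected_k = selected_k,
                 labels = labels_by_cond, time_ms = times_by_cond,
                 map_windows = map_windows,
                 gev = list(before_constraint = gev_before,
                            after_constraint = gev_after),
                 solutions = sweep$solutions,
                 criterion_scores = criterion_scores,
                 frame = fr, params = params),
            class = "microstate_segmentation")
}

#' @rdname segment_microstates
#' @export
segment_grand_averages <- segment_microstates

#' @export
print.microstate_segmentation <- function(x, ...) {
  cat(sprintf(
    "<microstate_segmentation> %d maps over %d condition(s), GEV = %.3f\n",
    x$selected_k, length(x$labels), x$gev$after_constraint$total))
  invisible(x)
}

#' @export
summary.microstate_segmentation <- function(object, ...) {
  cat(sprintf("Microstate segmentation: selected k = %d (of %d solutions)\n",
              object$selected_k,
              sum(!vapply(object$solutions, is.null, logical(1)))))
  cat(sprintf("GEV before/after temporal constraint: %.4f / %.4f\n",
              object$gev$before_constraint$total,
              object$gev$after_constraint$total))
  for (cn in names(object$map_windows)) {
    w <- object$map_windows[[cn]]
    cat(sprintf("  %s: %d segment(s)\n", cn, nrow(w)))
    for (i in seq_len(nrow(w))) {
      cat(sprintf("    map %d: %.1f .. %.1f ms\n",
                  w$map_id[i], w$t_start_ms[i], w$t_end_ms[i]))
    }
  }
  invisible(object)
}

#' @export
coef.microstate_segmentation <- function(object, ...) object$templates

#' @export
plot.microstate_segmentation <- function(x, ...) {
  conds <- names(x$labels)
  op <- graphics::par(mfrow = c(length(conds), 1L),
                      mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  cols <- grDevices::hcl.colors(max(2L, x$selected_k), "Dark 3")
  for (cn in conds) {
    tm <- x$time_ms[[cn]]
    sel <- x$frame$condition == match(cn, names(x$labels))
    g <- x$frame$gfp[sel]
    lab <- x$labels[[cn]]
    graphics::plot(tm, g, type = "n", xlab = "", ylab = "GFP (uV)",
                   main = cn, ...)
    for (m in seq_len(x$selected_k)) {
      idx <- which(!is.na(lab) & lab == m)
      if (length(idx)) {
        graphics::segments(tm[idx], 0, tm[idx], g[idx], col = cols[m])
      }
    }
    graphics::lines(tm, g)
  }
  invisible(x)
}
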