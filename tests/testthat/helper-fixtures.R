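# Shared fixtures and independent oracles, all built in code at test time.

# k exactly orthogonal zero-mean unit-GFP maps from Helmert contrasts
orthogonal_templates <- function(nch, k) {
  H <- stats::contr.helmert(nch)[, seq_len(k), drop = FALSE]
  apply(H, 2L, normalize_map)
}

# Evoked ERP whose analysis window tiles the templates in consecutive
# blocks, each scaled by a strictly positive, varying envelope.
tile_erp <- function(templates, block_len, sfreq = 1000, amp = 2,
                     language = "L1", embodiment = "motor") {
  k <- ncol(templates)
  env <- amp * (1 + 0.5 * sin(seq_len(block_len)))
  X <- do.call(cbind, lapply(seq_len(k), function(m) {
    tcrossprod(templates[, m], env)
  }))
  evoked_erp(X, sfreq, 0, subject_id = "tile", language = language,
             embodiment = embodiment)
}

true_tile_labels <- function(k, block_len) rep(seq_len(k), each = block_len)

# grand averages of a simulated dataset, one per design cell
cell_grand_averages <- function(ds) {
  cells <- vapply(ds$erps, function(e) paste(e$language, e$embodiment),
                  character(1))
  lapply(unique(cells), function(cl) {
    grand_average(lapply(ds$erps[cells == cl], average_reference))
  })
}

# best template-to-template matching over all permutations (k <= 5)
best_assignment_corr <- function(fitted, truth) {
  k <- ncol(truth)
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1L, function(p) length(unique(p)) == k), ,
                 drop = FALSE]
  best <- -Inf; best_cors <- NULL
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    cors <- vapply(seq_len(k), function(m) {
      abs(spatial_correlation(fitted[, p[m]], truth[, m]))
    }, numeric(1))
    if (sum(cors) > best) { best <- sum(cors); best_cors <- cors }
  }
  best_cors
}

# Exhaustive search over all k^T labelings of the columns of X, scoring each
# with the package's GEV definition and centroid convention (mean of the
# original maps, GFP-normalized). Independent of the AAHC code path.
exhaustive_best_gev <- function(X, k) {
  X <- sweep(X, 2L, colMeans(X), "-")
  nch <- nrow(X); Tn <- ncol(X)
  g <- sqrt(colMeans(X^2))
  Vn <- sweep(X, 2L, g, "/")
  g2 <- g^2; tot <- sum(g2)
  best <- 0
  lab <- rep(1L, Tn)
  repeat {
    gev <- 0
    for (m in seq_len(k)) {
      mem <- which(lab == m)
      if (!length(mem)) next
      cen <- rowMeans(X[, mem, drop = FALSE])
      cen <- cen - mean(cen)
      gc <- sqrt(mean(cen^2))
      if (gc < 1e-12) next
      cen <- cen / gc
      cc <- crossprod(Vn[, mem, drop = FALSE], cen) / nch
      gev <- gev + sum(g2[mem] * cc^2)
    }
    best <- max(best, gev / tot)
    # next labeling (odometer)
    i <- 1L
    while (i <= Tn) {
      lab[i] <- lab[i] + 1L
      if (lab[i] <= k) break
      lab[i] <- 1L; i <- i + 1L
    }
    if (i > Tn) break
  }
  best
}

# Independent RM-ANOVA oracle through stats::aov error strata
aov_rm_oracle <- function(df, value = "value") {
  df$y <- df[[value]]
  df$s <- factor(df$subject_id)
  df$A <- factor(df$language)
  df$B <- factor(df$embodiment)
  fit <- summary(stats::aov(y ~ A * B + Error(s / (A * B)), data = df))
  pick <- function(stratum, term) {
    tab <- fit[[stratum]][[1L]]
    i <- grep(term, trimws(rownames(tab)), fixed = TRUE)[1L]
    c(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  rbind(language = pick("Error: s:A", "A"),
        embodiment = pick("Error: s:B", "B"),
        interaction = pick("Error: s:A:B", "A:B"))
}

# balanced random 2x2 within dataset
random_rm_data <- function(n, seed) {
  set.seed(seed)
  expand.grid(subject_id = sprintf("S%02d", seq_len(n)),
              language = c("L1", "L2"),
              embodiment = c("motor", "non-motor"),
              stringsAsFactors = FALSE) |>
    transform(value = rnorm(4L * n, mean = 10, sd = 2))
}

# Power through the Poisson mixture of central F distributions -- an
# independent route to the noncentral F tail probability.
power_mixture_oracle <- function(n, alpha = 0.05, f = 0.25, rho = 0.5,
                                 epsilon = 1, m = 4) {
  lambda <- f^2 * n * m * epsilon / (1 - rho)
  df1 <- (m - 1) * epsilon
  df2 <- (n - 1) * (m - 1) * epsilon
  crit <- qf(1 - alpha, df1, df2)
  j <- 0:400
  w <- dpois(j, lambda / 2)
  tail <- vapply(j, function(jj) {
    pf(crit * df1 / (df1 + 2 * jj), df1 + 2 * jj, df2, lower.tail = FALSE)
  }, numeric(1))
  sum(w * tail)
}

# per-subject mean GFP in a window, straight from the raw data
window_mean_gfp <- function(erp, win) {
  tms <- erp_times(erp)
  sel <- tms >= win[1] & tms < win[2]
  mean(gfp(average_reference(erp$data[, sel, drop = FALSE])))
}

# index of the fitted template best matching a planted one
match_template <- function(fitted, planted_map) {
  which.max(abs(apply(fitted, 2L, spatial_correlation, v = planted_map)))
}

run_lengths_ms <- function(lab, sfreq) {
  r <- rle(ifelse(is.na(lab), -1L, lab))
  r$lengths[r$values > 0L] / sfreq * 1000
}
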