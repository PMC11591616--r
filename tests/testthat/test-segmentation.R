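test_that("AAHC exactly recovers planted orthogonal maps", {
  tmpl <- orthogonal_templates(32, 4)
  gas <- list(tile_erp(tmpl, block_len = 30))
  sw <- aahc_cluster(gas, segmentation_params(
    k_max = 6, analysis_window_ms = c(0, 1e6)))
  sol <- sw$solutions[[4]]
  cors <- best_assignment_corr(sol$templates, tmpl)
  expect_true(all(cors >= 0.999))
  expect_gte(sol$gev_total, 0.999)
})

test_that("k = 1 GEV equals the brute-force GFP-weighted squared correlation", {
  set.seed(31)
  X <- matrix(rnorm(16 * 40), 16, 40)
  ga <- evoked_erp(X, 1000, 0)
  sw <- aahc_cluster(list(ga), segmentation_params(
    k_max = 3, analysis_window_ms = c(0, 1e6)))
  sol <- sw$solutions[[1]]
  # direct GEV oracle
  X0 <- sweep(X, 2, colMeans(X), "-")
  g <- apply(X0, 2, gfp)
  cc <- vapply(seq_len(40), function(t)
    spatial_correlation(X0[, t], sol$templates[, 1]), numeric(1))
  expect_equal(sol$gev_total, sum((g * cc)^2) / sum(g^2), tolerance = 1e-10)
})

test_that("AAHC is near the exhaustive optimum on toy instances", {
  set.seed(32)
  for (case in list(list(T = 12, k = 2), list(T = 9, k = 3))) {
    # structured toy: planted polarity-consistent maps + substantial noise
    tmpl <- orthogonal_templates(4, case$k)
    lab <- sample(rep(seq_len(case$k), length.out = case$T))
    X <- tmpl[, lab] %*% diag(runif(case$T, 1, 3)) +
      matrix(rnorm(4 * case$T, sd = 0.5), 4)
    best <- exhaustive_best_gev(X, case$k)
    sw <- aahc_cluster(list(evoked_erp(X, 1000, 0)),
                       segmentation_params(k_max = case$k,
                                           analysis_window_ms = c(0, 1e6)))
    got <- sw$solutions[[case$k]]$gev_total
    expect_gte(got, best * 0.98)
    expect_lte(got, best + 1e-10)
  }
})

test_that("per-map GEV follows the definition on a hand instance", {
  # 2 channels, 3 samples; maps along [1,-1] with strengths 2, 4, 6
  X <- matrix(c(2, -2, 4, -4, -6, 6), 2, 3)
  tmpl <- matrix(c(1, -1, -1, 1), 2, 2)
  out <- compute_gev(X, tmpl, labels = c(1L, 1L, 2L))
  # by hand: GFP = 2, 4, 6; corr with map1 = 1, 1, -1; with map2 = -1,-1,1
  # GEV_1 = (2^2 + 4^2) / (4 + 16 + 36); GEV_2 = 6^2 / 56
  expect_equal(out$per_map, c(20 / 56, 36 / 56))
  expect_equal(out$total, 1)
  # unlabeled samples lower the total
  out2 <- compute_gev(X, tmpl, labels = c(1L, NA, 2L))
  expect_equal(out2$total, (4 + 36) / 56)
  out3 <- compute_gev(X, tmpl, labels = rep(NA_integer_, 3))
  expect_equal(out3$total, 0)
  # data exactly one template under a varying positive envelope
  env <- c(1, 2.5, 0.3)
  X1 <- matrix(c(1, -1), 2) %*% t(env)
  expect_equal(compute_gev(X1, tmpl, labels = rep(1L, 3))$total, 1)
  expect_error(compute_gev(matrix(0, 2, 3), tmpl, labels = rep(1L, 3)),
               "zero total GFP")
})

test_that("temporal constraint dissolves only sub-threshold runs", {
  sfreq <- 1024
  tmpl <- orthogonal_templates(16, 3)
  # 40-sample runs of maps 1 and 2 flanking a 5-sample run of map 3
  lab <- c(rep(1L, 40), rep(3L, 5), rep(2L, 40))
  X <- tmpl[, lab] * 2
  sm <- apply_temporal_constraint(lab, 10, sfreq, X, tmpl)
  expect_true(all(run_lengths_ms(sm, sfreq) >= 10))
  expect_false(any(sm == 3L))
  # samples keep their best-correlated flanking map: all map-3 samples kept
  # their own topography, so they split by correlation with maps 1 and 2
  expect_true(all(sm[1:40] == 1L) && all(sm[46:85] == 2L))
  # a run of 11 ms (12 samples) is preserved
  lab2 <- c(rep(1L, 40), rep(3L, 12), rep(2L, 40))
  X2 <- tmpl[, lab2] * 2
  sm2 <- apply_temporal_constraint(lab2, 10, sfreq, X2, tmpl)
  expect_identical(sm2, lab2)
  # min_segment_ms = 0 is a no-op
  expect_identical(apply_temporal_constraint(lab, 0, sfreq, X, tmpl), lab)
})

test_that("degenerate all-short labelings fall back to the best single map", {
  sfreq <- 128
  tmpl <- orthogonal_templates(16, 2)
  lab <- rep(c(1L, 2L), 10)     # every run 1 sample = 7.8 ms
  X <- tmpl[, lab]
  expect_warning(
    sm <- apply_temporal_constraint(lab, 10, sfreq, X, tmpl),
    "globally best")
  expect_equal(length(unique(sm)), 1L)
})

test_that("criterion convergence recovers the planted number of maps", {
  hits <- 0L
  for (s in 1:50) {
    cfg <- synth_config(seed = 300 + s, n_subjects = 4, n_channels = 32,
                        sfreq = 256, noise_sd = 0.05)
    ds <- simulate_dataset(cfg)
    sw <- aahc_cluster(cell_grand_averages(ds), segmentation_params(k_max = 8))
    if (meta_criterion_select(sw)$selected_k == 4L) hits <- hits + 1L
  }
  expect_gte(hits, 48L)          # >= 95% of 50 seeds
})

test_that("criteria stay parsimonious on pure noise", {
  for (s in 1:6) {
    set.seed(400 + s)
    gas <- lapply(1:4, function(i)
      evoked_erp(matrix(rnorm(32 * 90), 32, 90), 128, 0))
    sw <- aahc_cluster(gas, segmentation_params(k_max = 8))
    expect_lte(meta_criterion_select(sw)$selected_k, 3L)
  }
})

test_that("the sweep records up to k_max solutions", {
  set.seed(33)
  ga <- evoked_erp(matrix(rnorm(16 * 60), 16, 60), 1000, 0)
  sw <- aahc_cluster(list(ga), segmentation_params(
    k_max = 20, analysis_window_ms = c(0, 1e6)))
  expect_equal(sum(!vapply(sw$solutions, is.null, logical(1))), 20L)
  expect_equal(max(which(!vapply(sw$solutions, is.null, logical(1)))), 20L)
})

test_that("k-sweep GEV is non-decreasing and the constraint can only lose GEV", {
  cfg <- synth_config(seed = 35, n_subjects = 4, n_channels = 32,
                      sfreq = 128, noise_sd = 0.5)
  ds <- simulate_dataset(cfg)
  gas <- cell_grand_averages(ds)
  seg <- segment_microstates(gas, segmentation_params(k_max = 8))
  gev_k <- vapply(seg$solutions, `[[`, numeric(1), "gev_total")
  expect_true(all(diff(gev_k) >= -1e-9))
  expect_gte(seg$gev$before_constraint$total,
             seg$gev$after_constraint$total - 1e-12)
})

test_that("exact copies of orthogonal templates cluster to GEV 1", {
  tmpl <- orthogonal_templates(24, 3)
  ga <- tile_erp(tmpl, block_len = 25)
  sw <- aahc_cluster(list(ga), segmentation_params(
    k_max = 5, analysis_window_ms = c(0, 1e6)))
  expect_gte(sw$solutions[[3]]$gev_total, 0.999)
})

test_that("segmentation windows recover the planted P1 and N1 windows", {
  cfg <- synth_config(seed = 37, n_subjects = 6, n_channels = 32,
                      sfreq = 512, noise_sd = 0.05)
  ds <- simulate_dataset(cfg)
  seg <- segment_microstates(cell_grand_averages(ds),
                             segmentation_params(k_max = 8))
  planted <- list(p1 = c(100, 150), n1 = c(150, 300))
  # overlap is judged over the signal-bearing part of the epoch (the union
  # of planted windows): outside it there is no field to segment and the
  # winner-take-all label of a pure-noise sample is arbitrary at any noise
  # level, so it carries no information about window recovery
  support <- c(100, 500)
  for (m in c(1L, 2L)) {
    fit_id <- match_template(seg$templates, ds$timeline$templates[, m])
    win <- planted[[m]]
    jac <- vapply(names(seg$labels), function(cn) {
      tm <- seg$time_ms[[cn]]
      lab <- seg$labels[[cn]]
      in_sup <- tm >= support[1] & tm < support[2]
      in_fit <- !is.na(lab) & lab == fit_id & in_sup
      in_true <- tm >= win[1] & tm < win[2]
      sum(in_fit & in_true) / sum(in_fit | in_true)
    }, numeric(1))
    expect_gte(mean(jac), 0.8)
  }
  # P1 and N1 land on distinct templates
  expect_false(match_template(seg$templates, ds$timeline$templates[, 1]) ==
                 match_template(seg$templates, ds$timeline$templates[, 2]))
})

test_that("identical grand averages give identical per-condition labelings", {
  set.seed(38)
  X <- matrix(rnorm(16 * 80), 16, 80)
  gas <- lapply(1:4, function(i) evoked_erp(X, 128, 0))
  seg <- segment_microstates(gas, segmentation_params(k_max = 6))
  for (j in 2:4) expect_identical(seg$labels[[1]], seg$labels[[j]])
})

test_that("segmentation is deterministic", {
  cfg <- synth_config(seed = 39, n_subjects = 3, n_channels = 16,
                      sfreq = 128, noise_sd = 0.5)
  gas <- cell_grand_averages(simulate_dataset(cfg))
  s1 <- segment_microstates(gas, segmentation_params(k_max = 6))
  s2 <- segment_microstates(gas, segmentation_params(k_max = 6))
  expect_identical(s1$templates, s2$templates)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$selected_k, s2$selected_k)
})
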