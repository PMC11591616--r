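test_that("back-fitting a noiseless template sequence is exact", {
  tmpl <- orthogonal_templates(16, 4)
  erp <- tile_erp(tmpl, block_len = 20, sfreq = 1000)
  bf <- backfit_subject(erp, tmpl, analysis_window_ms = c(0, 80))
  expect_identical(bf$labels, true_tile_labels(4, 20))
  expect_equal(sum(bf$records$gev), 1)
  expect_equal(bf$records$duration_ms, rep(20, 4))
})

test_that("winner-take-all ties break toward the lower map index", {
  # disjoint-support templates so the tie is exact in floating point
  tmpl <- cbind(normalize_map(c(1, -1, 0, 0)), normalize_map(c(0, 0, 1, -1)))
  tie_map <- normalize_map(tmpl[, 1] + tmpl[, 2])
  erp <- evoked_erp(cbind(tie_map, tie_map) * 2, 1000, 0)
  bf <- backfit_subject(erp, tmpl, analysis_window_ms = c(0, 10))
  expect_true(all(bf$labels == 1L))
})

test_that("maps that never win get zero GEV, GFP and duration", {
  tmpl <- orthogonal_templates(16, 3)
  erp <- tile_erp(tmpl[, 1, drop = FALSE], block_len = 30, sfreq = 1000)
  bf <- backfit_subject(erp, tmpl, analysis_window_ms = c(0, 30))
  expect_equal(bf$records$gev[2:3], c(0, 0))
  expect_equal(bf$records$mean_gfp[2:3], c(0, 0))
  expect_equal(bf$records$duration_ms[2:3], c(0, 0))
})

test_that("per-sample label accuracy is high at window SNR >= 5", {
  noise_sd <- 0.25
  cfg <- synth_config(seed = 51, n_subjects = 50, n_channels = 32,
                      sfreq = 128, noise_sd = noise_sd)
  mont <- make_montage(32, seed = 51)
  tmpl <- make_templates(mont, 4, seed = 51, min_separation = 0.5)
  tl <- gt_timeline(tmpl)
  acc <- num <- 0
  for (s in 1:50) {
    e <- simulate_subject_erp(cfg, tl, s, "L1", "motor")
    bf <- backfit_subject(e, tl$templates, c(0, 700))
    tms <- bf$time_ms
    truth <- rep(NA_integer_, length(tms))
    strong <- rep(FALSE, length(tms))
    for (i in seq_len(nrow(tl$entries))) {
      en <- tl$entries[i, ]
      inside <- tms >= en$t_start_ms & tms < en$t_end_ms
      truth[inside] <- en$map_id
      u <- (tms[inside] - en$t_start_ms) / (en$t_end_ms - en$t_start_ms)
      env <- en$amplitude_uV * 0.5 * (1 - cos(2 * pi * u))
      strong[inside] <- env >= 5 * noise_sd     # instantaneous SNR >= 5
    }
    sel <- strong & !is.na(bf$labels)
    acc <- acc + sum(bf$labels[sel] == truth[sel])
    num <- num + sum(sel)
  }
  expect_gte(acc / num, 0.9)
})

test_that("RM-ANOVA finds nothing in constant data", {
  df <- random_rm_data(6, seed = 52)
  df$value <- 5
  out <- suppressWarnings(rm_anova_2x2(df))
  ss <- attr(out, "ss")
  expect_equal(unname(ss[c("A", "B", "AB")]), c(0, 0, 0))
})

test_that("RM-ANOVA matches the aov error-strata oracle", {
  # small printed dataset, n = 3
  hand <- data.frame(
    subject_id = rep(c("s1", "s2", "s3"), each = 4),
    language = rep(c("L1", "L1", "L2", "L2"), 3),
    embodiment = rep(c("motor", "non-motor"), 6),
    value = c(10.2, 11.5, 12.1, 11.9,
              9.8, 10.9, 13.0, 12.2,
              10.5, 11.0, 12.8, 12.5))
  got <- rm_anova_2x2(hand)
  want <- aov_rm_oracle(hand)
  expect_equal(got$F, unname(want[, "F"]), tolerance = 1e-8)
  expect_equal(got$p, unname(want[, "p"]), tolerance = 1e-8)
  # random designs across sizes
  for (n in c(3, 5, 10)) {
    df <- random_rm_data(n, seed = 520 + n)
    got <- rm_anova_2x2(df)
    want <- aov_rm_oracle(df)
    expect_equal(got$F, unname(want[, "F"]), tolerance = 1e-8)
    expect_equal(got$df1, rep(1L, 3))
    expect_equal(got$df2, rep(n - 1L, 3))
    # partial eta^2 identity for 1-df effects
    expect_equal(got$eta2_partial, got$F / (got$F + n - 1), tolerance = 1e-10)
    expect_true(all(got$eta2_partial >= got$eta2_generalized))
    expect_true(all(got$eta2_generalized >= 0 & got$eta2_partial <= 1))
  }
})

test_that("RM-ANOVA is invariant to subject relabeling", {
  df <- random_rm_data(8, seed = 53)
  perm <- sample(unique(df$subject_id))
  df2 <- df
  df2$subject_id <- perm[match(df$subject_id, unique(df$subject_id))]
  expect_equal(rm_anova_2x2(df)$F, rm_anova_2x2(df2)$F)
})

test_that("RM-ANOVA rejects incomplete designs naming the subject", {
  df <- random_rm_data(4, seed = 54)
  df <- df[-2, ]
  expect_error(rm_anova_2x2(df), "S02")
})

test_that("zero error variance is reported as a degenerate F", {
  df <- random_rm_data(4, seed = 55)
  df$value <- ifelse(df$language == "L2", 2, 1)    # no subject variability
  expect_warning(out <- rm_anova_2x2(df), "degenerate")
  expect_equal(out$F[out$effect == "language"], Inf)
  expect_equal(out$p[out$effect == "language"], 0)
})

test_that("a planted embodiment effect is detected with high power", {
  rej <- 0L
  for (s in 1:100) {
    cfg <- synth_config(seed = 5000 + s, n_subjects = 29, n_channels = 16,
                        sfreq = 128, noise_sd = 0.5)
    ds <- simulate_dataset(cfg)
    df <- do.call(rbind, lapply(ds$erps, function(e) {
      data.frame(subject_id = e$subject_id, language = e$language,
                 embodiment = e$embodiment,
                 value = window_mean_gfp(e, c(150, 300)))
    }))
    out <- rm_anova_2x2(df)
    if (out$p[out$effect == "embodiment"] < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 100, 0.8)
})

test_that("power-based sample size reproduces the a-priori calculation", {
  res <- rm_anova_power_n(alpha = 0.05, f = 0.25, power_target = 0.8,
                          rho = 0.5, epsilon = 1, n_groups = 1,
                          n_measurements = 4)
  expect_equal(res$n, 24L)
  expect_gte(res$power, 0.8)
  # minimality against the Poisson-mixture oracle
  expect_lt(power_mixture_oracle(23), 0.8)
  expect_gte(power_mixture_oracle(24), 0.8)
  expect_equal(rm_anova_power(24), power_mixture_oracle(24),
               tolerance = 1e-8)
})

test_that("required n responds monotonically to f, alpha and rho", {
  base <- rm_anova_power_n()$n
  expect_lte(rm_anova_power_n(f = 0.5)$n, base)
  expect_lte(rm_anova_power_n(alpha = 0.1)$n, base)
  # lambda grows as 1/(1-rho): higher rho needs fewer subjects
  expect_lte(rm_anova_power_n(rho = 0.7)$n, rm_anova_power_n(rho = 0.3)$n)
  expect_error(rm_anova_power_n(alpha = 0), "alpha")
  expect_error(rm_anova_power_n(f = -1), "f must be")
})

test_that("GEV is conserved across maps for every subject and cell", {
  cfg <- synth_config(seed = 57, n_subjects = 4, n_channels = 16,
                      sfreq = 128, noise_sd = 0.5)
  ds <- simulate_dataset(cfg)
  res <- run_full_analysis(ds, segmentation_params(k_max = 6))
  sums <- aggregate(gev ~ subject_id + language + embodiment,
                    data = res$backfit, FUN = sum)
  expect_true(all(sums$gev <= 1 + 1e-12))
  expect_true(all(sums$gev > 0))
})

test_that("the full analysis is deterministic", {
  cfg <- synth_config(seed = 58, n_subjects = 3, n_channels = 16,
                      sfreq = 128, noise_sd = 0.5)
  ds <- simulate_dataset(cfg)
  r1 <- run_full_analysis(ds, segmentation_params(k_max = 5))
  r2 <- run_full_analysis(ds, segmentation_params(k_max = 5))
  expect_identical(r1$anova, r2$anova)
  expect_identical(r1$backfit, r2$backfit)
})

test_that("predict() back-fits a segmentation to new data", {
  cfg <- synth_config(seed = 59, n_subjects = 3, n_channels = 16,
                      sfreq = 128, noise_sd = 0.5)
  ds <- simulate_dataset(cfg)
  seg <- segment_microstates(cell_grand_averages(ds),
                             segmentation_params(k_max = 5))
  one <- predict(seg, ds$erps[[1]])
  expect_named(one, c("labels", "time_ms", "records"))
  all_rec <- predict(seg, ds$erps[1:4])
  expect_equal(nrow(all_rec), 4L * seg$selected_k)
})
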