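test_that("the analysis table joins losslessly, keeps missing cells, and
          rejects duplicates", {
  cfg <- test_config(missing_1khz_32k_rate = 0.35)
  co <- generate_cohort(cfg, seed = 23)
  spec16 <- efr_stimulus("ram", 16000, 1000)
  efr <- extract_efr_table(co, methods = "f0")
  abr <- extract_abr_table(co)
  dp <- extract_dpoae_table(co)
  tab <- build_analysis_table(co, efr, abr, dp)
  expect_lte(nrow(tab), 57 * 2)
  expect_equal(anyDuplicated(tab[, c("ear_id", "frequency_hz")]), 0)
  # missingness matches the generator's per-ear flags exactly
  flagged <- co$ears$ear_id[co$ears$missing_1khz_32k]
  miss32 <- tab$ear_id[tab$frequency_hz == 32000 & is.na(tab$ram_1000_f0)]
  expect_setequal(miss32, flagged)
  expect_true(all(!is.na(tab$ram_1000_f0[tab$frequency_hz == 16000])))
  # duplicated measurement rows are rejected
  expect_error(build_analysis_table(co, rbind(efr, efr[1, ]), abr, dp),
               "duplicate")
})

test_that("intercept-only fit predicts the mean; exact linear structure is
          recovered", {
  tab <- make_model_table(50, beta = c(abr_80 = 0.3), sigma = 0, seed = 3)
  fit0 <- fit_model(model_spec(), tab)
  expect_equal(unname(fit0$coefficients[1]), mean(tab$synapses_per_ihc))
  expect_equal(fit0$k, 2)
  fit1 <- fit_model(model_spec("abr_80"), tab)
  expect_equal(unname(fit1$coefficients), c(2, 0.3), tolerance = 1e-9)
  expect_equal(fit1$k, 3)
})

test_that("planted two-predictor coefficients are recovered within 3 SE", {
  tab <- make_model_table(200, beta = c(abr_80 = 0.4, dpoae_40 = -0.2),
                          sigma = 1.5, seed = 29)
  fit <- fit_model(model_spec("abr_80", adjust = "dpoae_40"), tab)
  se <- sqrt(diag(vcov(fit$fit)))
  truth <- c(2, 0.4, -0.2)
  expect_true(all(abs(fit$coefficients - truth) < 3 * se))
  # rank deficiency is reported with the offending column
  tab$dpoae_55 <- tab$dpoae_40
  expect_error(fit_model(model_spec("abr_80", adjust = "dpoae_55"),
                         dplyr::mutate(tab, dpoae_55 = dpoae_40,
                                       abr_80 = dpoae_40)),
               "collinear")
})

test_that("rmse matches hand cases and the mean-prediction identity", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 2), c(1, 1)), 1)
  withr::with_seed(31, {
    y <- rnorm(500, 10, 3)
    expect_equal(rmse(y, rep(mean(y), 500)),
                 sd(y) * sqrt(499 / 500), tolerance = 1e-12)
  })
  expect_error(rmse(numeric(), numeric()), "nonempty")
  expect_error(rmse(1:3, 1:2), "equal length")
})

test_that("grouped folds partition the non-test ears and never split an
          ear", {
  tab <- make_model_table(35, beta = c(M = 0.5), sigma = 1, seed = 37)
  tab$group[tab$ear_id %in% sprintf("e%03d", 1:8)] <- "acute_noise"
  cfg <- cv_config(k_folds = 10, repeats = 3, seed = 11)
  res <- repeated_grouped_cv(model_spec(), tab, cfg)
  pool_ears <- sort(unique(tab$ear_id[tab$group != "acute_noise"]))
  for (r in unique(res$per_fold$repeat_i)) {
    folds <- res$per_fold$val_ears[res$per_fold$repeat_i == r]
    sizes <- lengths(folds)
    expect_lte(diff(range(sizes)), 1)
    expect_setequal(unlist(folds), pool_ears)     # exact partition
    expect_equal(anyDuplicated(unlist(folds)), 0) # no ear in two folds
  }
  # identical seed, identical assignment and results
  res2 <- repeated_grouped_cv(model_spec(), tab, cfg)
  expect_identical(res$per_fold, res2$per_fold)
  expect_error(repeated_grouped_cv(model_spec(), tab,
                                   cv_config(k_folds = 30, seed = 1)),
               "fewer ears")
})

test_that("intercept-only CV RMSE matches the outcome SD and a generating
          predictor reaches the noise floor", {
  # one 200-ear draw's realized noise SD wobbles by a few percent, so the
  # sigma-recovery checks average over four independent data realizations
  cv0 <- sapply(1:4, function(s) {
    tab0 <- make_model_table(200, beta = c(M = 0), sigma = 2,
                             seed = 40 + s)
    repeated_grouped_cv(model_spec(), tab0,
                        cv_config(test_group = NULL, seed = 5))$mean_val
  })
  expect_lt(abs(mean(cv0) - 2) / 2, 0.05)
  ratio <- sapply(1:4, function(s) {
    tab1 <- make_model_table(200, beta = c(M = 0.3), sigma = 1,
                             seed = 60 + s)
    cv_m <- repeated_grouped_cv(model_spec_raw("M"), tab1,
                                cv_config(test_group = NULL, seed = 5))
    cv_i <- repeated_grouped_cv(model_spec(), tab1,
                                cv_config(test_group = NULL, seed = 5))
    expect_lt(cv_m$mean_val, cv_i$mean_val)
    cv_m$mean_val
  })
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("the acute test set stays out of training and is scored by every
          fold's model", {
  tab <- make_model_table(30, beta = c(M = 0.5), sigma = 1, seed = 47)
  tab$group[tab$ear_id %in% sprintf("e%03d", 1:6)] <- "acute_noise"
  res <- repeated_grouped_cv(model_spec(), tab,
                             cv_config(repeats = 2, seed = 3))
  test_ears <- unique(tab$ear_id[tab$group == "acute_noise"])
  expect_true(all(!unlist(res$per_fold$val_ears) %in% test_ears))
  expect_true(all(is.finite(res$per_fold$rmse_test)))
  expect_equal(nrow(res$per_fold), 20)
})

test_that("delta RMSE pairs models with matched adjustment and is zero
          against itself", {
  tab <- make_model_table(40, beta = c(M = 0.5, dpoae_40 = -0.1,
                                       dpoae_threshold = 0.05),
                          sigma = 1, seed = 53)
  cfg <- cv_config(test_group = NULL, seed = 9)
  specs <- list(model_spec(), model_spec(character(), adjust = "dpoae_40"),
                model_spec_raw("M"),
                model_spec_raw("M", adjust = "dpoae_40"))
  res <- lapply(specs, repeated_grouped_cv, table = tab, cfg = cfg)
  d <- delta_rmse_vs_reference(res, character())
  self <- d[d$model_id == res[[1]]$spec$model_id, ]
  expect_equal(self$delta_rmse, 0)
  expect_equal(self$delta_sem, 0)
  expect_true(all(d$paired))
  # adding the generating predictor reduces error under both adjustments
  gain <- d[grepl("^M", d$model_id), ]
  expect_true(all(gain$delta_rmse < 0))
  expect_error(delta_rmse_vs_reference(res[3:4], "abr_80"), "no reference")
})
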