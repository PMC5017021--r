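test_that("log2fc follows the treated-over-control convention", {
  expect_equal(log2fc(5, 5), 0)
  expect_equal(log2fc(14, 1), log2(14))
  expect_equal(log2(14), 3.807355, tolerance = 1e-6)
  expect_equal(log2fc(1, 2), -1)
  expect_error(log2fc(0, 0), "both means")
})

test_that("bh_adjust equals a brute-force step-up on fixed and random vectors", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.001, 1.0)), c(0.002, 1.0))
  set.seed(123)
  for (i in 1:200) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("moderated t with d0 = 0 equals the classical pooled-variance t", {
  sim <- simulate_study(design = study_design(modes = "RP_pos"),
                        n_features = 100, seed = 21)
  logt <- log_transform(normalize_cell_number(sim$tables$RP_pos, sim$meta,
                                              sim$counts))
  fit <- fit_moderated(logt, sim$meta, 24,
                       moderation = structure(list(d0 = 0, s0_sq = 1),
                                              class = "ModerationParams"))
  m <- sim$meta
  trt <- m$injection_id[m$role == "sample" & m$time_h == 24 & m$condition == "treated"]
  ctl <- m$injection_id[m$role == "sample" & m$time_h == 24 & m$condition == "control"]
  classical <- apply(logt$intensities, 1, function(v) {
    s2p <- (sum((v[trt] - mean(v[trt]))^2) + sum((v[ctl] - mean(v[ctl]))^2)) / 4
    (mean(v[trt]) - mean(v[ctl])) / sqrt(s2p * (1 / 3 + 1 / 3))
  })
  expect_equal(fit$results$t, unname(classical), tolerance = 1e-12)
})

test_that("d0 = Inf collapses every posterior variance to the prior", {
  sim <- simulate_study(design = study_design(modes = "RP_pos"),
                        n_features = 50, seed = 22)
  logt <- log_transform(sim$tables$RP_pos)
  fit <- fit_moderated(logt, sim$meta, 12,
                       moderation = structure(list(d0 = Inf, s0_sq = 0.04),
                                              class = "ModerationParams"))
  expect_true(all(fit$results$s2_post == 0.04))
})

test_that("moment matching agrees with an independent solve of the moment equations", {
  # oracle: solve E[log s2] and Var[log s2] equations numerically on a grid,
  # independent of the package's trigamma-inversion path
  set.seed(31)
  d <- 4
  d0_true <- 5; s0_true <- 0.05
  s2 <- s0_true * stats::rf(2000, d, d0_true)
  est <- estimate_moderation(s2, d)
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  target <- var(e) - trigamma(d / 2)
  f <- function(d0) trigamma(d0 / 2) - target
  oracle_d0 <- uniroot(f, c(0.1, 500), tol = 1e-12)$root
  oracle_s0 <- exp(mean(e) + digamma(oracle_d0 / 2) - log(oracle_d0 / 2))
  expect_equal(est$d0, oracle_d0, tolerance = 1e-6)
  expect_equal(est$s0_sq, oracle_s0, tolerance = 1e-6)
  # and the estimates recover the generating hyperparameters roughly
  expect_gt(est$d0, 3); expect_lt(est$d0, 8)
})

test_that("moderated fit agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  sim <- simulate_study(design = study_design(modes = "RP_pos"),
                        effects = effect_spec(0.1, 6, 2),
                        n_features = 2000, seed = 23)
  logt <- log_transform(normalize_cell_number(sim$tables$RP_pos, sim$meta,
                                              sim$counts))
  fit <- fit_moderated(logt, sim$meta, 24)
  m <- sim$meta
  trt <- m$injection_id[m$role == "sample" & m$time_h == 24 & m$condition == "treated"]
  ctl <- m$injection_id[m$role == "sample" & m$time_h == 24 & m$condition == "control"]
  X <- logt$intensities[, c(trt, ctl)]
  design <- cbind(intercept = 1, treated = rep(c(1, 0), each = 3))
  lfit <- limma::eBayes(limma::lmFit(X, design))
  expect_equal(fit$moderation$d0, lfit$df.prior, tolerance = 1e-4)
  expect_equal(fit$moderation$s0_sq, lfit$s2.prior, tolerance = 1e-4)
  expect_equal(fit$results$t, unname(lfit$t[, "treated"]), tolerance = 1e-4)
  expect_equal(fit$results$log2fc, unname(lfit$coefficients[, "treated"]),
               tolerance = 1e-10)
})

test_that("null simulations yield near-zero significant counts after BH", {
  sim <- simulate_study(design = study_design(modes = "RP_pos"),
                        effects = effect_spec(fraction_differential = 0),
                        n_features = 500, seed = 24)
  qc <- apply_qc(sim$tables$RP_pos, sim$meta, sim$counts, sim$is_ids$RP_pos)
  d <- run_differential(qc$table, sim$meta)
  cnt <- count_significant(d, alpha = 0.05)
  expect_true(all(cnt$n_significant <= 0.05 * nrow(qc$table$intensities)))
  expect_equal(count_significant(d, alpha = 0)$n_significant, rep(0L, 6))
})

test_that("detection rate at 24 h is non-decreasing in effect size", {
  rates <- vapply(c(0.5, 1, 2), function(fc) {
    sim <- simulate_study(design = study_design(modes = "RP_pos"),
                          effects = effect_spec(0.2, 6, fc),
                          n_features = 500, background_fraction = 0, seed = 25)
    norm <- normalize_cell_number(sim$tables$RP_pos, sim$meta, sim$counts)
    fit <- fit_moderated(log_transform(norm), sim$meta, 24)
    truth <- sim$truth[match(fit$results$feature_id, sim$truth$feature_id), ]
    mean(fit$results$q[truth$is_differential] < 0.05)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("estimated log2FC error shrinks as noise vanishes", {
  mae <- vapply(c(0.2, 0.05, 0.01), function(cv) {
    sim <- simulate_study(design = study_design(modes = "RP_pos"),
                          effects = effect_spec(0.1, 6, 2),
                          noise_cv = cv, bio_cv = 0, n_features = 300,
                          background_fraction = 0, seed = 26)
    norm <- normalize_cell_number(sim$tables$RP_pos, sim$meta, sim$counts)
    fit <- fit_moderated(log_transform(norm), sim$meta, 24)
    truth <- sim$truth[match(fit$results$feature_id, sim$truth$feature_id), ]
    mean(abs(fit$results$log2fc[truth$is_differential] -
               truth$lfc_24[truth$is_differential]))
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
  expect_lt(mae[3], 0.02)
})
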