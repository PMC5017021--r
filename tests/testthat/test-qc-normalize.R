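test_that("rsd matches hand-computed values and rejects degenerate input", {
  expect_equal(rsd(c(10, 10, 10)), 0)
  expect_equal(rsd(c(1, 2, 3)), 0.5)
  expect_equal(rsd(c(100, 120)), sqrt(200) / 110, tolerance = 1e-12)
  expect_error(rsd(c(5)), "at least 2")
  expect_error(rsd(c(0, 0)), "mean")
})

test_that("noise threshold removes strictly-below-threshold features per mode", {
  meta <- tiny_meta()
  defaults <- c(RP_pos = 1e5, RP_neg = 2e4, HILIC_pos = 1.5e5, HILIC_neg = 5e4)
  for (mode in names(defaults)) {
    thr <- defaults[[mode]]
    tab <- tiny_table(meta, n_feat = 3, fill = 0, mode = mode)
    smp <- meta$injection_id[meta$role == "sample"]
    tab$intensities["F001", smp[1]] <- thr - 1   # just below: removed
    tab$intensities["F002", smp[1]] <- thr       # exactly at: retained
    tab$intensities["F003", smp[1]] <- thr + 1
    res <- apply_noise_threshold(tab, meta, qc_config())
    expect_equal(res$removed, "F001")
    expect_equal(res$table$features$feature_id, c("F002", "F003"))
  }
  # threshold 0 is the identity
  tab <- tiny_table(meta, n_feat = 5)
  res0 <- apply_noise_threshold(tab, meta, qc_config(noise_threshold = c(RP_pos = 0)))
  expect_equal(nrow(res0$table$intensities), 5)
})

test_that("blank filter applies the median/20%/30-of-36 rule inclusively", {
  meta <- tiny_meta()
  smp <- meta$injection_id[meta$role == "sample"]
  blanks <- meta$injection_id[meta$role == "blank"]
  tab <- tiny_table(meta, n_feat = 3, fill = 100)
  # F001: blank median 0 -> always retained
  tab$intensities["F001", blanks] <- 0
  # F002: blank median 21 vs all samples at 100 -> holds in 0 samples -> removed
  tab$intensities["F002", blanks] <- 21
  # F003: blank median 20; 30 samples at 100 (20 <= 20), 6 at 50 -> exactly 30 -> retained
  tab$intensities["F003", blanks] <- 20
  tab$intensities["F003", smp[31:36]] <- 50
  res <- blank_filter(tab, meta, qc_config())
  expect_equal(res$removed, "F002")
  expect_equal(res$table$features$feature_id, c("F001", "F003"))
})

test_that("blank filter matches a brute-force per-feature oracle on random features", {
  set.seed(41)
  n <- 1000
  meta <- tiny_meta()
  smp <- meta$injection_id[meta$role == "sample"]
  blanks <- meta$injection_id[meta$role == "blank"]
  X <- matrix(runif(n * nrow(meta), 0, 200), n, nrow(meta),
              dimnames = list(NULL, meta$injection_id))
  tab <- feature_table(
    data.frame(feature_id = sprintf("F%04d", 1:n), mz = runif(n, 70, 950),
               rt = runif(n, 0, 900)),
    X, "RP_pos")
  res <- blank_filter(tab, meta, qc_config())
  oracle_keep <- vapply(seq_len(n), function(i) {
    B <- median(X[i, blanks])
    hits <- 0L
    for (s in smp) if (B <= 0.2 * X[i, s]) hits <- hits + 1L
    hits >= 30L
  }, logical(1))
  expect_identical(res$table$features$feature_id,
                   tab$features$feature_id[oracle_keep])
})

test_that("internal-standard gate is strict at 20% and dataset-level", {
  meta <- tiny_meta()
  smp <- meta$injection_id[meta$role == "sample"]
  tab <- tiny_table(meta, n_feat = 2)
  # constant IS -> RSD 0 -> pass
  g <- is_gate(tab, meta, c("F001", "F002"), qc_config())
  expect_true(g$pass)
  expect_equal(unname(g$is_rsd), c(0, 0))
  # one IS with sample values cycling 1,2,3 -> RSD far above 0.2 -> fail
  tab$intensities["F002", smp] <- rep(c(1, 2, 3), 12)
  expect_false(is_gate(tab, meta, c("F001", "F002"), qc_config())$pass)
  # an RSD exactly at the threshold fails the strict < comparison
  tab2 <- tiny_table(meta, n_feat = 1, fill = 5)
  tab2$intensities["F001", smp] <- rep(c(4, 5, 6), 12)
  r <- rsd(tab2$intensities["F001", smp])
  expect_false(is_gate(tab2, meta, "F001", qc_config(is_rsd_max = r))$pass)
  expect_true(is_gate(tab2, meta, "F001",
                      qc_config(is_rsd_max = r + 1e-12))$pass)
  expect_error(is_gate(tab2, meta, "missing_id", qc_config()), "missing_id")
})

test_that("pool RSD filter is strict at 25%", {
  meta <- tiny_meta(n_pools = 5)
  pools <- meta$injection_id[meta$role == "pool"]
  tab <- tiny_table(meta, n_feat = 3, fill = 100)
  # F001 constant in pools -> retained
  # F002: pool values 1,2,3,2,2 -> RSD well above 0.25 -> removed
  tab$intensities["F002", pools] <- c(1, 2, 3, 1, 3)
  # F003: pools c(3,3,5,5,4): mean 4, sd exactly 1 -> RSD exactly 0.25 -> removed
  tab$intensities["F003", pools] <- c(3, 3, 5, 5, 4)
  expect_equal(sd(c(3, 3, 5, 5, 4)) / mean(c(3, 3, 5, 5, 4)), 0.25)
  res <- pool_rsd_filter(tab, meta, qc_config())
  expect_equal(res$table$features$feature_id, "F001")
  expect_equal(sort(res$removed), c("F002", "F003"))
})

test_that("cell-number normalization divides samples by their group mean count", {
  meta <- tiny_meta()
  tab <- tiny_table(meta, n_feat = 1, fill = 1e6)
  grid <- expand.grid(time_h = c(0, 1, 3, 6, 12, 24),
                      condition = c("control", "treated"),
                      stringsAsFactors = FALSE)
  counts <- cell_counts(grid$condition, grid$time_h, rep(2e5, nrow(grid)))
  norm <- normalize_cell_number(tab, meta, counts)
  smp <- meta$injection_id[meta$role == "sample"]
  expect_equal(unname(norm$intensities[1, smp]), rep(5, 36))
  # blanks and pools keep raw areas
  others <- meta$injection_id[meta$role != "sample"]
  expect_equal(unname(norm$intensities[1, others]), rep(1e6, 14))
  # treated count half of control at 24 h, equal raw areas -> treated 2x control
  counts2 <- counts
  counts2$mean_cells[counts2$condition == "treated" & counts2$time_h == 24] <- 1e5
  norm2 <- normalize_cell_number(tab, meta, counts2)
  expect_equal(unname(norm2$intensities[1, "T_24h_r1"]),
               2 * unname(norm2$intensities[1, "C_24h_r1"]))
  # missing count errors
  expect_error(normalize_cell_number(tab, meta, counts[-1, ]), "no cell count")
})

test_that("TIC and housekeeping normalizations behave as column scalings", {
  meta <- tiny_meta()
  tab <- tiny_table(meta, n_feat = 2, fill = 1)
  smp <- meta$injection_id[meta$role == "sample"]
  tab$intensities["F001", smp] <- 3
  tab$intensities["F002", smp] <- 1
  tic <- normalize_alternative(tab, meta, "TIC")
  expect_equal(unname(tic$intensities[, smp[1]]), c(0.75, 0.25))
  # TIC is invariant to column scaling
  tab2 <- tab
  tab2$intensities[, smp] <- tab2$intensities[, smp] * 7
  tic2 <- normalize_alternative(tab2, meta, "TIC")
  expect_equal(tic2$intensities[, smp], tic$intensities[, smp])
  hk <- normalize_alternative(tab, meta, "housekeeping", feature_id = "F001")
  expect_equal(unname(hk$intensities["F001", smp]), rep(1, 36))
  expect_error(normalize_alternative(tab, meta, "housekeeping",
                                     feature_id = "nope"), "housekeeping")
})

test_that("the QC chain reconciles stage counts and is idempotent", {
  sim <- simulate_study(design = study_design(modes = "RP_pos"),
                        n_features = 300, seed = 8)
  qc <- apply_qc(sim$tables$RP_pos, sim$meta, sim$counts, sim$is_ids$RP_pos)
  st <- qc$report$stages
  expect_equal(st$n_input, st$n_removed + st$n_retained)
  expect_equal(st$n_input[-1], st$n_retained[-length(st$n_retained)])
  expect_equal(nrow(qc$report$removed), sum(st$n_removed))
  # idempotence of each filter on the raw (unnormalized) scale: re-applying
  # to an already-filtered table removes nothing
  cfg <- qc_config()
  raw <- apply_qc(sim$tables$RP_pos, sim$meta, counts = NULL,
                  sim$is_ids$RP_pos)$table
  again <- apply_noise_threshold(raw, sim$meta, cfg)
  expect_equal(again$stage$n_removed, 0)
  again2 <- pool_rsd_filter(blank_filter(raw, sim$meta, cfg)$table,
                            sim$meta, cfg)
  expect_equal(again2$stage$n_removed, 0)
})

test_that("raising ratio/RSD thresholds never shrinks, raising noise never grows, the retained set", {
  sim <- simulate_study(design = study_design(modes = "RP_pos"),
                        n_features = 200, seed = 9)
  tab <- sim$tables$RP_pos; meta <- sim$meta
  kept <- function(cfg) {
    t1 <- apply_noise_threshold(tab, meta, cfg)$table
    t2 <- blank_filter(t1, meta, cfg)$table
    pool_rsd_filter(t2, meta, cfg)$table$features$feature_id
  }
  base <- kept(qc_config())
  looser <- kept(qc_config(blank_ratio = 0.4, pool_rsd_max = 0.5))
  expect_true(all(base %in% looser))
  harsher_noise <- kept(qc_config(noise_threshold = c(RP_pos = 5e5)))
  expect_true(all(harsher_noise %in% base))
})

test_that("blank filter removes exactly the constructed background features", {
  sim <- simulate_study(design = study_design(modes = "RP_pos"),
                        noise_cv = 0.02, bio_cv = 0, n_features = 200,
                        background_fraction = 0.15, seed = 10)
  tab <- sim$tables$RP_pos
  res <- blank_filter(tab, sim$meta, qc_config())
  truth <- sim$truth
  # background features have blank median ~50% of sample intensity; IS
  # features are spiked into blanks at full level, so they fail too
  expected_removed <- truth$feature_id[truth$is_background | truth$is_internal_standard]
  expect_setequal(res$removed, expected_removed)
})
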