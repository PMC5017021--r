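test_that("ppm error is the scaled relative deviation", {
  expect_equal(ppm_error(100, 100), 0)
  expect_equal(ppm_error(180.06339, 180.06300),
               1e6 * (180.06339 - 180.06300) / 180.06300)
  expect_equal(ppm_error(180.06339, 180.06300), 2.166, tolerance = 1e-3)
  expect_gt(abs(ppm_error(100.0006, 100.0000)), 5)
  expect_error(ppm_error(100, 0), "positive")
})

test_that("neutral mass arithmetic inverts the adduct shift", {
  expect_equal(neutral_mass(308.09108, "pos"), 307.08380, tolerance = 1e-9)
  expect_equal(neutral_mass(306.07652, "neg"), 307.08380, tolerance = 1e-9)
  for (ad in c("[M+H]+", "[M-H]-")) {
    expect_equal(neutral_mass(mz_from_neutral(307.08380, ad), adduct = ad),
                 307.08380)
  }
  expect_error(neutral_mass(100, adduct = "[M+Na]+"), "unknown adduct")
})

test_that("cross-mode matching recovers planted shared compounds exactly", {
  set.seed(61)
  # masses on a 0.5 u grid: any two distinct grid points are > 500 ppm apart
  grid <- seq(100, 899.5, by = 0.5)
  picks <- sample(grid, 190)
  shared <- picks[1:10]
  dec_a <- picks[11:100]
  # decoys in table b offset by 0.05 u (>= 55 ppm from anything in table a)
  dec_b <- picks[101:190] + 0.05
  make_tab <- function(masses, mode) {
    ad <- if (grepl("pos", mode)) 1.00728 else -1.00728
    feature_table(
      data.frame(feature_id = sprintf("%s_%03d", mode, seq_along(masses)),
                 mz = masses + ad, rt = seq_along(masses)),
      matrix(1, length(masses), 2, dimnames = list(NULL, c("i1", "i2"))),
      mode)
  }
  tab_a <- make_tab(c(shared, dec_a), "RP_pos")
  tab_b <- make_tab(c(shared, dec_b), "HILIC_neg")
  res <- cross_mode_match(list(tab_a, tab_b), tol_ppm = 5)
  # brute-force all-pairs oracle
  na <- neutral_mass(tab_a$features$mz, "pos")
  nb <- neutral_mass(tab_b$features$mz, "neg")
  oracle <- sum(outer(na, nb, function(x, y) abs(1e6 * (x - y) / y) <= 5))
  expect_equal(nrow(res$matches), oracle)
  expect_equal(nrow(res$matches), 10)
  expect_equal(unname(res$venn[["HILIC_neg+RP_pos"]]), 10)
  # identical tables share everything
  res2 <- cross_mode_match(list(tab_a, make_tab(c(shared, dec_a), "RP_neg")))
  expect_true(all(table(res2$groups$group) == 2))
})

test_that("matching is symmetric and monotone in tolerance", {
  set.seed(62)
  masses <- runif(50, 100, 900)
  ta <- feature_table(
    data.frame(feature_id = sprintf("a%02d", 1:50), mz = masses + 1.00728,
               rt = 1:50),
    matrix(1, 50, 1, dimnames = list(NULL, "x")), "RP_pos")
  tb <- feature_table(
    data.frame(feature_id = sprintf("b%02d", 1:50),
               mz = masses * (1 + rnorm(50, 0, 4e-6)) - 1.00728, rt = 1:50),
    matrix(1, 50, 1, dimnames = list(NULL, "x")), "RP_neg")
  m_ab <- cross_mode_match(list(ta, tb), tol_ppm = 5)$matches
  m_ba <- cross_mode_match(list(tb, ta), tol_ppm = 5)$matches
  expect_equal(nrow(m_ab), nrow(m_ba))
  m_wide <- cross_mode_match(list(ta, tb), tol_ppm = 20)$matches
  expect_gte(nrow(m_wide), nrow(m_ab))
})

test_that("MS2 similarity is 1 for self, 0 for disjoint, cosine for overlaps", {
  sp <- cbind(mz = c(50, 80, 120), intensity = c(1, 0.5, 0.2))
  expect_equal(ms2_similarity(sp, sp), 1.0)
  sp2 <- cbind(mz = c(200, 300), intensity = c(1, 1))
  expect_equal(ms2_similarity(sp, sp2), 0.0)
  # half-overlapping equal-intensity peaks: cosine on aligned vectors
  a <- cbind(mz = c(100, 200), intensity = c(1, 1))
  b <- cbind(mz = c(100, 300), intensity = c(1, 1))
  # aligned vectors (sqrt weights): a = (1,1,0), b = (1,0,1) -> cos = 0.5
  expect_equal(ms2_similarity(a, b), 0.5)
  expect_error(ms2_similarity(a[0, , drop = FALSE], b), "empty")
})

test_that("identification levels reproduce the evidence truth table exhaustively", {
  flags <- expand.grid(ms2_db = c(FALSE, TRUE), ref_rt = c(FALSE, TRUE),
                       ref_ms2 = c(FALSE, TRUE))
  for (i in seq_len(nrow(flags))) {
    f <- flags[i, ]
    got <- assign_level(TRUE, f$ms2_db, f$ref_rt, f$ref_ms2)
    want <- if (f$ref_rt && f$ref_ms2) "1"
            else if (f$ref_rt) "1a"
            else if (f$ms2_db || f$ref_ms2) "2"
            else "putative"
    expect_equal(got, want, label = paste(unlist(f), collapse = "/"))
  }
  expect_error(assign_level(FALSE), "mass match")
})

test_that("annotation recovers spiked compounds with no false identities", {
  meta <- tiny_meta()
  tab <- tiny_table(meta, n_feat = 30, fill = 1e6)
  # decoy masses: far (>= 20 ppm) from every compound
  set.seed(63)
  tab$features$mz <- runif(30, 400, 900)
  cmp <- compound_table(
    c("glutathione", "citrulline", "glycerophosphocholine"),
    c(307.08380, 175.09569, 257.10282),
    ref_rt = c(420, 300, NA),
    has_db_ms2 = c(TRUE, FALSE, TRUE),
    ms2 = list(cbind(c(76.02, 84.04, 130.05), c(1, 0.6, 0.3)), NULL, NULL))
  spiked <- spike_known_compounds(tab, cmp, adduct = "[M+H]+")
  obs_ms2 <- list()
  obs_ms2[[spiked$spiked$feature_id[1]]] <-
    cbind(c(76.02, 84.04, 130.05), c(900, 500, 260))
  ann <- annotate_features(spiked$table, cmp, tol_ppm = 5, ms2 = obs_ms2)
  expect_setequal(ann$feature_id, spiked$spiked$feature_id)
  expect_equal(ann$compound[match(spiked$spiked$feature_id, ann$feature_id)],
               cmp$name)
  # glutathione: RT match + reference MS2 match -> level 1
  expect_equal(ann$level[ann$compound == "glutathione"], "1")
  # citrulline: RT only -> 1a; GPC: mass only (no observed MS2, no ref RT)
  expect_equal(ann$level[ann$compound == "citrulline"], "1a")
  expect_equal(ann$level[ann$compound == "glycerophosphocholine"], "putative")
  expect_true(all(abs(ann$ppm) <= 5))
})
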