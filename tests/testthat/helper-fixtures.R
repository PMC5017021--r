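# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# A minimal hand-built study: n_feat features, 36 samples (2 x 6 x 3),
# n_blanks blanks, n_pools pools, with every intensity settable.
tiny_meta <- function(n_blanks = 6, n_pools = 8) {
  tp <- c(0, 1, 3, 6, 12, 24)
  grid <- expand.grid(replicate = 1:3, time_h = tp,
                      condition = c("control", "treated"),
                      stringsAsFactors = FALSE)
  ids <- sprintf("%s_%gh_r%d",
                 ifelse(grid$condition == "control", "C", "T"),
                 grid$time_h, grid$replicate)
  blank_ids <- if (n_blanks > 0) sprintf("blank_%d", seq_len(n_blanks)) else character(0)
  pool_ids <- if (n_pools > 0) sprintf("pool_%d", seq_len(n_pools)) else character(0)
  sample_metadata(
    injection_id = c(ids, blank_ids, pool_ids),
    role = c(rep("sample", nrow(grid)), rep("blank", n_blanks),
             rep("pool", n_pools)),
    condition = c(grid$condition, rep("none", n_blanks + n_pools)),
    time_h = c(grid$time_h, rep(NA, n_blanks + n_pools)),
    replicate = c(grid$replicate, rep(NA, n_blanks + n_pools))
  )
}

tiny_table <- function(meta, n_feat = 4, fill = 1e6, mode = "RP_pos") {
  X <- matrix(fill, nrow = n_feat, ncol = nrow(meta),
              dimnames = list(NULL, meta$injection_id))
  feature_table(
    data.frame(feature_id = sprintf("F%03d", seq_len(n_feat)),
               mz = seq(100, 100 + n_feat - 1), rt = rep(60, n_feat)),
    X, mode)
}

# Independent brute-force BH step-up, written from the definition.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)  # rank of p[i] in ascending order
    cands <- sapply(rank_i:m, function(j) m * p[ord[j]] / j)
    q[i] <- min(1, min(cands))
  }
  q
}
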