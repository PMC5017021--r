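#' Quality-control configuration
#'
#' Thresholds for the feature-level QC chain. The per-mode noise-threshold
#' defaults are the values used for the intracellular datasets of the
#' emulated study (RP_pos 100,000; RP_neg 20,000; HILIC_pos 150,000;
#' HILIC_neg 50,000). The blank rule retains a feature only if its median
#' blank intensity does not exceed `blank_ratio` (20%) of the sample
#' intensity in at least `blank_min_pass` analytical samples (30 of 36 by
#' default; generalized to ceil(5/6 x n) for other sample counts). The
#' internal-standard and pool RSD gates are strict (`<`).
#'
#' @param noise_threshold named numeric vector of per-mode thresholds; modes
#'   absent from the vector fall back to `default_noise`.
#' @param default_noise fallback noise threshold.
#' @param blank_ratio maximum allowed blank/sample intensity ratio.
#' @param blank_min_pass samples in which the blank rule must hold; `NULL`
#'   means ceil(5/6 x number of analytical samples).
#' @param is_rsd_max internal-standard RSD gate (strict <).
#' @param pool_rsd_max pooled-QC RSD filter threshold (strict <).
#' @return list of class `QCConfig`.
#' @export
qc_config <- function(noise_threshold = c(RP_pos = 100000, RP_neg = 20000,
                                          HILIC_pos = 150000, HILIC_neg = 50000),
                      default_noise = 0,
                      blank_ratio = 0.20,
                      blank_min_pass = NULL,
                      is_rsd_max = 0.20,
                      pool_rsd_max = 0.25) {
  stopifnot(blank_ratio > 0, blank_ratio <= 1,
            is_rsd_max > 0, is_rsd_max <= 1,
            pool_rsd_max > 0, pool_rsd_max <= 1,
            all(noise_threshold >= 0), default_noise >= 0)
  structure(list(noise_threshold = noise_threshold,
                 default_noise = default_noise,
                 blank_ratio = blank_ratio,
                 blank_min_pass = blank_min_pass,
                 is_rsd_max = is_rsd_max,
                 pool_rsd_max = pool_rsd_max),
            class = "QCConfig")
}

noise_threshold_for <- function(cfg, mode) {
  if (mode %in% names(cfg$noise_threshold)) {
    unname(cfg$noise_threshold[[mode]])
  } else {
    cfg$default_noise
  }
}

blank_min_pass_for <- function(cfg, n_samples) {
  if (!is.null(cfg$blank_min_pass)) {
    if (cfg$blank_min_pass > n_samples) {
      stop("blank_min_pass exceeds the number of analytical samples")
    }
    return(cfg$blank_min_pass)
  }
  ceiling(5 / 6 * n_samples)
}

#' Relative standard deviation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values numeric vector of at least two non-negative values with a
#'   positive mean. Zeros participate as true zeros.
#' @return the RSD as a proportion.
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("RSD needs at least 2 values")
  m <- mean(values)
  if (m <= 0) stop("RSD undefined for non-positive mean")
  stats::sd(values) / m
}

filter_stage <- function(stage, keep, table) {
  data.frame(stage = stage,
             n_input = length(keep),
             n_removed = sum(!keep),
             n_retained = sum(keep),
             stringsAsFactors = FALSE)
}

subset_table <- function(table, keep) {
  feature_table(table$features[keep, , drop = FALSE],
                table$intensities[keep, , drop = FALSE],
                table$mode)
}

#' Noise-threshold filter
#'
#' Removes features whose maximum intensity across analytical samples falls
#' below the per-mode noise threshold (strict <; a feature exactly at the
#' threshold is retained).
#'
#' @param table a `FeatureTable`.
#' @param meta matching `SampleMetadata`.
#' @param cfg a `QCConfig`.
#' @return list with filtered `table`, `stage` summary row and `removed`
#'   feature ids.
#' @export
apply_noise_threshold <- function(table, meta, cfg = qc_config()) {
  thr <- noise_threshold_for(cfg, table$mode)
  smp <- meta$injection_id[meta$role == "sample"]
  mx <- apply(table$intensities[, smp, drop = FALSE], 1, max)
  keep <- mx >= thr
  list(table = subset_table(table, keep),
       stage = filter_stage("noise_threshold", keep, table),
       removed = table$features$feature_id[!keep])
}

#' Blank-ratio filter
#'
#' Per feature, the median intensity across blank injections must not exceed
#' `blank_ratio` of the sample intensity in at least `blank_min_pass`
#' analytical samples; otherwise the feature is flagged as chemical noise /
#' background and removed. The comparison is inclusive (blank median equal
#' to 20% of the sample intensity passes).
#'
#' @inheritParams apply_noise_threshold
#' @return list with filtered `table`, `stage` summary row and `removed` ids.
#' @export
blank_filter <- function(table, meta, cfg = qc_config()) {
  blanks <- meta$injection_id[meta$role == "blank"]
  if (length(blanks) == 0L) stop("blank filter requires at least one blank injection")
  smp <- meta$injection_id[meta$role == "sample"]
  min_pass <- blank_min_pass_for(cfg, length(smp))
  B <- apply(table$intensities[, blanks, drop = FALSE], 1, stats::median)
  S <- table$intensities[, smp, drop = FALSE]
  n_pass <- rowSums(B <= cfg$blank_ratio * S)
  keep <- n_pass >= min_pass
  list(table = subset_table(table, keep),
       stage = filter_stage("blank_filter", keep, table),
       removed = table$features$feature_id[!keep])
}

#' Internal-standard gate
#'
#' Dataset-level quality gate: the RSD of each internal standard across all
#' analytical samples must be strictly below `is_rsd_max`. A failing gate
#' disqualifies the whole dataset from differential analysis; it does not
#' drop features.
#'
#' @inheritParams apply_noise_threshold
#' @param is_feature_ids ids of the internal-standard features; all must be
#'   present in the table.
#' @return list with `pass` (logical), `is_rsd` (named RSDs) and `threshold`.
#' @export
is_gate <- function(table, meta, is_feature_ids, cfg = qc_config()) {
  missing <- setdiff(is_feature_ids, table$features$feature_id)
  if (length(missing) > 0L) {
    stop("internal-standard feature(s) absent from table: ",
         paste(missing, collapse = ", "))
  }
  smp <- meta$injection_id[meta$role == "sample"]
  vals <- table$intensities[is_feature_ids, smp, drop = FALSE]
  is_rsd <- apply(vals, 1, rsd)
  names(is_rsd) <- is_feature_ids
  list(pass = all(is_rsd < cfg$is_rsd_max), is_rsd = is_rsd,
       threshold = cfg$is_rsd_max)
}

#' Pooled-QC stability filter
#'
#' Retains only features whose RSD across pooled-QC injections is strictly
#' below `pool_rsd_max` (technically stable features).
#'
#' @inheritParams apply_noise_threshold
#' @return list with filtered `table`, `stage` summary row and `removed` ids.
#' @export
pool_rsd_filter <- function(table, meta, cfg = qc_config()) {
  pools <- meta$injection_id[meta$role == "pool"]
  if (length(pools) < 2L) stop("pool RSD filter requires at least 2 pool injections")
  P <- table$intensities[, pools, drop = FALSE]
  pool_rsd <- apply(P, 1, function(v) {
    if (mean(v) <= 0) Inf else stats::sd(v) / mean(v)
  })
  keep <- pool_rsd < cfg$pool_rsd_max
  list(table = subset_table(table, keep),
       stage = filter_stage("pool_rsd", keep, table),
       removed = table$features$feature_id[!keep])
}

#' Cell-number normalization
#'
#' Divides the peak area of each feature in each analytical sample by the
#' mean viable cell number of that sample's (condition, time) group, turning
#' areas into area-per-cell and removing the confounding of treatment effect
#' with growth arrest / cell death. Blank and pool columns are left at raw
#' areas (they serve QC only).
#'
#' @param table a `FeatureTable`.
#' @param meta matching `SampleMetadata`.
#' @param counts a `CellCounts` covering every (condition, time) present.
#' @return the normalized `FeatureTable`.
#' @export
normalize_cell_number <- function(table, meta, counts) {
  X <- table$intensities
  smp <- which(meta$role == "sample")
  key_counts <- paste(counts$condition, counts$time_h, sep = "/")
  for (j in smp) {
    k <- paste(meta$condition[j], meta$time_h[j], sep = "/")
    i <- match(k, key_counts)
    if (is.na(i)) stop("no cell count for ", k)
    n_cells <- counts$mean_cells[i]
    if (!is.finite(n_cells) || n_cells <= 0) stop("non-positive cell count for ", k)
    X[, meta$injection_id[j]] <- X[, meta$injection_id[j]] / n_cells
  }
  feature_table(table$features, X, table$mode)
}

#' Alternative sample normalizations
#'
#' `"TIC"` divides each sample column by its total ion current (column sum);
#' `"housekeeping"` divides by the intensity of a designated housekeeping
#' metabolite feature in the same column. Blanks and pools are untouched.
#'
#' @inheritParams normalize_cell_number
#' @param method `"TIC"` or `"housekeeping"`.
#' @param feature_id housekeeping feature id (required for
#'   `method = "housekeeping"`).
#' @return the normalized `FeatureTable`.
#' @export
normalize_alternative <- function(table, meta, method = c("TIC", "housekeeping"),
                                  feature_id = NULL) {
  method <- match.arg(method)
  X <- table$intensities
  smp <- meta$injection_id[meta$role == "sample"]
  if (method == "TIC") {
    for (id in smp) {
      tot <- sum(X[, id])
      if (tot <= 0) stop("zero total ion current in sample ", id)
      X[, id] <- X[, id] / tot
    }
  } else {
    if (is.null(feature_id) || !feature_id %in% table$features$feature_id) {
      stop("housekeeping feature not present in table")
    }
    for (id in smp) {
      hk <- X[feature_id, id]
      if (hk <= 0) stop("zero housekeeping intensity in sample ", id)
      X[, id] <- X[, id] / hk
    }
  }
  feature_table(table$features, X, table$mode)
}

#' Run the full QC chain on one dataset
#'
#' Fixed stage order: noise threshold, blank filter, internal-standard gate,
#' pooled-QC RSD filter, then cell-number normalization. The filter report
#' reconciles exactly: every stage's input equals the previous stage's
#' retained count, and every removed feature carries its removal reason.
#' If the internal-standard gate fails, filtering stops after the gate and
#' the result is marked unusable for differential analysis.
#'
#' @param table a `FeatureTable`.
#' @param meta matching `SampleMetadata`.
#' @param counts a `CellCounts` (used for normalization; `NULL` skips it).
#' @param is_feature_ids internal-standard feature ids; `NULL` skips the gate.
#' @param cfg a `QCConfig`.
#' @return list of class `QCResult`: `table` (filtered, normalized),
#'   `report` (`FilterReport`: `stages` data.frame and `removed` data.frame
#'   of feature_id/stage), `is_gate` (gate result or `NULL`), `usable`
#'   (logical).
#' @export
apply_qc <- function(table, meta, counts = NULL, is_feature_ids = NULL,
                     cfg = qc_config()) {
  table0 <- table
  stages <- list()
  removed <- list()
  note <- function(res) {
    stages[[length(stages) + 1L]] <<- res$stage
    if (length(res$removed) > 0L) {
      removed[[length(removed) + 1L]] <<- data.frame(
        feature_id = res$removed, stage = res$stage$stage,
        stringsAsFactors = FALSE)
    }
    res$table
  }
  table <- note(apply_noise_threshold(table, meta, cfg))
  table <- note(blank_filter(table, meta, cfg))
  gate <- NULL
  usable <- TRUE
  if (!is.null(is_feature_ids)) {
    # dataset-level gate, computed on the unfiltered table: the internal
    # standards are spiked into every injection (blanks included), so they
    # legitimately fail the blank rule themselves
    gate <- is_gate(table0, meta, is_feature_ids, cfg)
    usable <- gate$pass
  }
  if (usable) {
    table <- note(pool_rsd_filter(table, meta, cfg))
    if (!is.null(counts)) table <- normalize_cell_number(table, meta, counts)
  }
  report <- structure(
    list(stages = do.call(rbind, stages),
         removed = if (length(removed) > 0L) do.call(rbind, removed) else
           data.frame(feature_id = character(0), stage = character(0))),
    class = "FilterReport")
  structure(list(table = table, report = report, is_gate = gate,
                 usable = usable),
            class = "QCResult")
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("FilterReport:\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}
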