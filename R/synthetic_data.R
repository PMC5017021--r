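#' Study design for the synthetic generator
#'
#' Mirrors the emulated study: two conditions (control, treated) over a time
#' course, with blanks and pooled-QC injections per dataset. The default
#' design is 2 conditions x 6 time points (0, 1, 3, 6, 12, 24 h) x 3
#' biological replicates = 36 analytical samples, acquired in four datasets
#' (RP/HILIC separation x pos/neg polarity).
#'
#' @param time_points_h strictly increasing non-negative hours.
#' @param n_replicates biological replicates per (condition, time); >= 2.
#' @param n_blanks,n_pools blank and pooled-QC injection counts.
#' @param modes dataset labels, each ending `_pos` or `_neg`.
#' @return list of class `StudyDesign`.
#' @export
study_design <- function(time_points_h = c(0, 1, 3, 6, 12, 24),
                         n_replicates = 3, n_blanks = 6, n_pools = 8,
                         modes = c("RP_pos", "RP_neg", "HILIC_pos", "HILIC_neg")) {
  if (length(modes) == 0L) stop("at least one mode is required")
  if (any(diff(time_points_h) <= 0) || any(time_points_h < 0)) {
    stop("time points must be non-negative and strictly increasing")
  }
  if (n_replicates < 2) stop("at least 2 replicates are required")
  if (n_blanks < 0 || n_pools < 0) stop("blank/pool counts must be >= 0")
  vapply(modes, polarity, character(1))
  structure(list(time_points_h = time_points_h,
                 n_replicates = as.integer(n_replicates),
                 n_blanks = as.integer(n_blanks),
                 n_pools = as.integer(n_pools),
                 modes = modes),
            class = "StudyDesign")
}

#' Treatment-effect specification for the synthetic generator
#'
#' True effects ramp in log2 space after an onset hour, emulating a toxicity
#' time course where differential regulation appears only at later time
#' points and keeps growing.
#'
#' @param fraction_differential proportion of features truly differential.
#' @param onset_h hour after which effects ramp; must lie within the design's
#'   time range.
#' @param max_log2fc signed log2 fold change reached at the last time point.
#' @param ramp_shape `"linear"` (log2FC grows linearly from 0 at onset to
#'   `max_log2fc` at the last time point) or `"step"` (full effect for all
#'   t > onset).
#' @return list of class `EffectSpec`.
#' @export
effect_spec <- function(fraction_differential = 0.1, onset_h = 6,
                        max_log2fc = 2, ramp_shape = c("linear", "step")) {
  ramp_shape <- match.arg(ramp_shape)
  if (fraction_differential < 0 || fraction_differential > 1) {
    stop("fraction_differential must be in [0, 1]")
  }
  if (!is.finite(max_log2fc)) stop("max_log2fc must be finite")
  structure(list(fraction_differential = fraction_differential,
                 onset_h = onset_h, max_log2fc = max_log2fc,
                 ramp_shape = ramp_shape),
            class = "EffectSpec")
}

#' True log2 fold-change trajectory of a differential feature
#'
#' @param effects an `EffectSpec`.
#' @param time_points_h hours at which to evaluate the ramp.
#' @return numeric vector of log2 fold changes, one per time point.
#' @export
effect_trajectory <- function(effects, time_points_h) {
  t_end <- max(time_points_h)
  if (effects$onset_h > t_end || effects$onset_h < min(time_points_h)) {
    stop("onset_h lies outside the time range")
  }
  if (effects$ramp_shape == "step") {
    return(ifelse(time_points_h > effects$onset_h, effects$max_log2fc, 0))
  }
  frac <- (time_points_h - effects$onset_h) / (t_end - effects$onset_h)
  pmax(frac, 0) * effects$max_log2fc
}

#' Viable-cell-number model for the synthetic generator
#'
#' Control cells grow exponentially; treated cells grow until a
#' growth-arrest hour and then decline exponentially — the behaviour that
#' makes cell-number normalization necessary.
#'
#' @param seed_density cells seeded at t = 0.
#' @param control_doubling_h control doubling time, hours.
#' @param treated_arrest_h hour at which treated growth arrests.
#' @param treated_decline_rate per-hour exponential decline after arrest.
#' @return list of class `CellCountModel`.
#' @export
cell_count_model <- function(seed_density = 2e5, control_doubling_h = 24,
                             treated_arrest_h = 6, treated_decline_rate = 0.05) {
  stopifnot(seed_density > 0, control_doubling_h > 0, treated_arrest_h >= 0,
            treated_decline_rate >= 0)
  structure(list(seed_density = seed_density,
                 control_doubling_h = control_doubling_h,
                 treated_arrest_h = treated_arrest_h,
                 treated_decline_rate = treated_decline_rate),
            class = "CellCountModel")
}

#' Evaluate a cell-count model
#'
#' @param cells a `CellCountModel`.
#' @param condition `"control"` or `"treated"`.
#' @param time_h hours.
#' @return mean viable cell numbers (always > 0).
#' @export
predict_cells <- function(cells, condition, time_h) {
  grow <- function(t) cells$seed_density * 2^(t / cells$control_doubling_h)
  if (condition == "control") return(grow(time_h))
  t_cap <- pmin(time_h, cells$treated_arrest_h)
  grow(t_cap) * exp(-cells$treated_decline_rate * pmax(time_h - cells$treated_arrest_h, 0))
}

# Multiplicative technical noise with coefficient of variation cv and unit
# expectation; exactly 1 when cv = 0.
noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

# Internal standards spiked at constant level into every injection.
IS_FEATURES <- data.frame(
  feature_id = c("IS_ethylparaben", "IS_nitrotyrosine"),
  neutral_mass = c(166.06299, 226.05897),
  stringsAsFactors = FALSE
)

#' Simulate a complete two-condition time-course metabolomics study
#'
#' Generates, per dataset mode, a dense feature x injection peak-area matrix
#' over analytical samples, blanks and pooled-QC injections, together with
#' sample metadata, viable-cell counts and a ground-truth table. Baseline
#' per-feature abundances are log-normal (log10 mean 6, sd 0.8). Technical
#' noise is multiplicative log-normal with coefficient of variation
#' `noise_cv` and unit expectation. Treated-sample intensities carry the
#' true effect `2^log2FC(t)` and all sample intensities scale with the
#' relative viable-cell number, so that raw areas confound treatment effect
#' and cell loss until cell-number normalization removes the latter. A
#' configurable fraction of "background" features has a blank median
#' exceeding 20% of the sample intensity (they fail the blank filter by
#' construction); all other features are absent from blanks (zero). Pools
#' are the mean composition of all analytical samples plus technical noise.
#' Two internal-standard features (ethylparaben, nitrotyrosine) are spiked
#' at a constant nominal level into every injection.
#'
#' Technical noise (`noise_cv`) applies to every feature in every injection
#' — including the internal standards, blanks and pools, whose RSDs gauge
#' exactly this noise. Biological between-replicate variability (`bio_cv`)
#' applies only to biological features in analytical samples: the internal
#' standards are spiked at a constant amount per injection, so biology does
#' not touch them.
#'
#' @param design a `StudyDesign`.
#' @param effects an `EffectSpec`.
#' @param cells a `CellCountModel`.
#' @param noise_cv technical coefficient of variation (>= 0).
#' @param bio_cv biological between-replicate coefficient of variation
#'   (>= 0).
#' @param n_features number of biological features per mode (internal
#'   standards are added on top).
#' @param background_fraction fraction of features constructed to violate
#'   the blank rule.
#' @param is_level nominal internal-standard peak area.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `tables` (named list of `FeatureTable` per mode),
#'   `meta` (`SampleMetadata`), `counts` (`CellCounts`), `truth`
#'   (data.frame: feature_id, mode, is_differential, is_background,
#'   is_internal_standard, compound, and one `lfc_<t>` column per time
#'   point), and `is_ids` (internal-standard feature ids).
#' @export
simulate_study <- function(design = study_design(),
                           effects = effect_spec(),
                           cells = cell_count_model(),
                           noise_cv = 0.1,
                           bio_cv = 0.2,
                           n_features = 1000,
                           background_fraction = 0.1,
                           is_level = 5e6,
                           seed = 1) {
  stopifnot(inherits(design, "StudyDesign"), noise_cv >= 0, bio_cv >= 0,
            n_features >= 1)
  set.seed(seed)

  tp <- design$time_points_h
  conditions <- c("control", "treated")
  smp <- expand.grid(replicate = seq_len(design$n_replicates),
                     time_h = tp, condition = conditions,
                     stringsAsFactors = FALSE)
  smp_ids <- sprintf("%s_%gh_r%d",
                     ifelse(smp$condition == "control", "C", "T"),
                     smp$time_h, smp$replicate)
  blank_ids <- if (design$n_blanks > 0) sprintf("blank_%d", seq_len(design$n_blanks)) else character(0)
  pool_ids <- if (design$n_pools > 0) sprintf("pool_%d", seq_len(design$n_pools)) else character(0)

  meta <- sample_metadata(
    injection_id = c(smp_ids, blank_ids, pool_ids),
    role = c(rep("sample", length(smp_ids)), rep("blank", length(blank_ids)),
             rep("pool", length(pool_ids))),
    condition = c(smp$condition, rep("none", length(blank_ids) + length(pool_ids))),
    time_h = c(smp$time_h, rep(NA_real_, length(blank_ids) + length(pool_ids))),
    replicate = c(smp$replicate, rep(NA_integer_, length(blank_ids) + length(pool_ids)))
  )

  grid <- expand.grid(time_h = tp, condition = conditions,
                      stringsAsFactors = FALSE)
  counts <- cell_counts(grid$condition, grid$time_h,
                        mapply(function(cond, t) predict_cells(cells, cond, t),
                               grid$condition, grid$time_h))

  ramp <- effect_trajectory(effects, tp)
  n_diff <- round(effects$fraction_differential * n_features)

  tables <- list()
  truth_all <- list()
  for (mode in design$modes) {
    pol <- polarity(mode)
    base <- 10^stats::rnorm(n_features, mean = 6, sd = 0.8)
    mz <- stats::runif(n_features, 70, 950)
    rt <- stats::runif(n_features, 30, 1200)
    diff_idx <- if (n_diff > 0) seq_len(n_diff) else integer(0)
    sign_fc <- rep(0, n_features)
    sign_fc[diff_idx] <- 1
    bg_idx <- if (background_fraction > 0) {
      sample(n_features, round(background_fraction * n_features))
    } else integer(0)

    # log2FC matrix: features x time points
    lfc <- outer(sign_fc, ramp)

    n_inj <- nrow(meta)
    X <- matrix(0, nrow = n_features, ncol = n_inj,
                dimnames = list(NULL, meta$injection_id))
    rel_cells <- mapply(function(cond, t) {
      if (is.na(t)) NA_real_ else predict_cells(cells, cond, t) / cells$seed_density
    }, meta$condition, meta$time_h)

    is_smp <- meta$role == "sample"
    t_index <- match(meta$time_h, tp)
    for (j in which(is_smp)) {
      fc <- if (meta$condition[j] == "treated") 2^lfc[, t_index[j]] else 1
      X[, j] <- base * fc * rel_cells[j] *
        noise_factor(n_features, bio_cv) * noise_factor(n_features, noise_cv)
    }
    # true mean composition of the analytical samples
    mean_comp <- rowMeans(sapply(which(is_smp), function(j) {
      fc <- if (meta$condition[j] == "treated") 2^lfc[, t_index[j]] else 1
      base * fc * rel_cells[j]
    }))
    for (j in which(meta$role == "pool")) {
      X[, j] <- mean_comp * noise_factor(n_features, noise_cv)
    }
    blank_level <- rep(0, n_features)
    blank_level[bg_idx] <- 0.5 * base[bg_idx]
    for (j in which(meta$role == "blank")) {
      X[, j] <- blank_level * noise_factor(n_features, noise_cv)
    }

    feature_id <- sprintf("%s_F%04d", mode, seq_len(n_features))
    features <- data.frame(feature_id = feature_id, mz = mz, rt = rt,
                           stringsAsFactors = FALSE)

    # append the internal standards at constant nominal level everywhere
    proton <- PROTON_MASS
    is_mz <- IS_FEATURES$neutral_mass + if (pol == "pos") proton else -proton
    is_rows <- matrix(rep(is_level, 2 * n_inj), nrow = 2,
                      dimnames = list(NULL, meta$injection_id))
    is_rows <- is_rows * rbind(noise_factor(n_inj, noise_cv),
                               noise_factor(n_inj, noise_cv))
    features <- rbind(features,
                      data.frame(feature_id = paste0(mode, "_", IS_FEATURES$feature_id),
                                 mz = is_mz, rt = c(600, 300),
                                 stringsAsFactors = FALSE))
    X <- rbind(X, is_rows)

    tables[[mode]] <- feature_table(features, X, mode)

    tr <- data.frame(
      feature_id = features$feature_id,
      mode = mode,
      is_differential = c(sign_fc == 1, FALSE, FALSE),
      is_background = c(seq_len(n_features) %in% bg_idx, FALSE, FALSE),
      is_internal_standard = c(rep(FALSE, n_features), TRUE, TRUE),
      compound = NA_character_,
      stringsAsFactors = FALSE
    )
    lfc_full <- rbind(lfc, matrix(0, 2, length(tp)))
    colnames(lfc_full) <- sprintf("lfc_%g", tp)
    truth_all[[mode]] <- cbind(tr, lfc_full)
  }

  truth <- do.call(rbind, truth_all)
  rownames(truth) <- NULL
  is_ids <- lapply(tables, function(tab) {
    grep("_IS_", tab$features$feature_id, value = TRUE, fixed = TRUE)
  })
  list(tables = tables, meta = meta, counts = counts, truth = truth,
       is_ids = is_ids)
}

#' Spike known compounds into a feature table
#'
#' Adds one feature per compound whose m/z is the ionized mass under the
#' given adduct, at a constant nominal intensity across all injections.
#' Used to exercise the annotation stage with known answers.
#'
#' @param table a `FeatureTable`.
#' @param compounds a `CompoundTable` (may be empty).
#' @param adduct `"[M+H]+"` or `"[M-H]-"`.
#' @param level nominal peak area for the spiked features.
#' @return list with the augmented `table` and `spiked` (data.frame:
#'   feature_id, compound).
#' @export
spike_known_compounds <- function(table, compounds, adduct = "[M+H]+",
                                  level = 1e6) {
  stopifnot(inherits(table, "FeatureTable"), inherits(compounds, "CompoundTable"))
  if (nrow(compounds) == 0L) {
    return(list(table = table, spiked = data.frame(feature_id = character(0),
                                                   compound = character(0))))
  }
  mzs <- mz_from_neutral(compounds$neutral_mass, adduct)
  ids <- sprintf("%s_SPK%02d", table$mode, seq_len(nrow(compounds)))
  rts <- ifelse(is.na(compounds$ref_rt), 600, compounds$ref_rt)
  features <- rbind(table$features,
                    data.frame(feature_id = ids, mz = mzs, rt = rts,
                               stringsAsFactors = FALSE))
  add <- matrix(level, nrow = nrow(compounds), ncol = ncol(table$intensities),
                dimnames = list(NULL, colnames(table$intensities)))
  intens <- rbind(table$intensities, add)
  list(table = feature_table(features, intens, table$mode),
       spiked = data.frame(feature_id = ids, compound = compounds$name,
                           stringsAsFactors = FALSE))
}
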