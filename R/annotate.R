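#' @importFrom stats setNames
NULL

# Proton mass (u) used for protonation/deprotonation adduct arithmetic.
PROTON_MASS <- 1.00728

# Adduct table: m/z = neutral mass + offset. Extensible.
ADDUCT_OFFSETS <- c("[M+H]+" = PROTON_MASS, "[M-H]-" = -PROTON_MASS)

adduct_offset <- function(adduct) {
  if (!adduct %in% names(ADDUCT_OFFSETS)) {
    stop("unknown adduct label: ", adduct)
  }
  unname(ADDUCT_OFFSETS[[adduct]])
}

default_adduct <- function(polarity) {
  switch(polarity, pos = "[M+H]+", neg = "[M-H]-",
         stop("unknown polarity: ", polarity))
}

#' Relative mass deviation in parts per million
#'
#' @param observed_mass,reference_mass masses in u; the reference must be
#'   positive.
#' @return 1e6 x (observed - reference) / reference.
#' @export
ppm_error <- function(observed_mass, reference_mass) {
  if (any(reference_mass <= 0)) stop("reference mass must be positive")
  1e6 * (observed_mass - reference_mass) / reference_mass
}

#' Neutral mass from an ion m/z, and its inverse
#'
#' Assumes single protonation/deprotonation: `[M+H]+` subtracts the proton
#' mass (1.00728 u); `[M-H]-` adds it.
#'
#' @param mz observed m/z (must exceed the adduct offset).
#' @param polarity `"pos"` or `"neg"`, used to pick the default adduct when
#'   `adduct` is `NULL`.
#' @param adduct explicit adduct label (overrides `polarity`).
#' @param neutral neutral monoisotopic mass for `mz_from_neutral`.
#' @return neutral monoisotopic mass (or ion m/z for `mz_from_neutral`).
#' @export
neutral_mass <- function(mz, polarity = NULL, adduct = NULL) {
  if (is.null(adduct)) adduct <- default_adduct(polarity)
  off <- adduct_offset(adduct)
  if (any(mz <= max(off, 0))) stop("m/z must exceed the adduct offset")
  mz - off
}

#' @rdname neutral_mass
#' @export
mz_from_neutral <- function(neutral, adduct) {
  neutral + adduct_offset(adduct)
}

#' Match features across separation/polarity modes by exact mass
#'
#' Computes the neutral mass of every feature (protonation/deprotonation per
#' the table's polarity), then groups features across tables whose neutral
#' masses agree within `tol_ppm`. Grouping is transitive (single-linkage on
#' the pairwise matches), and the per-region counts report how many mass
#' groups were observed in each combination of modes (the regions of a Venn
#' diagram over the tables).
#'
#' @param tables list of >= 2 `FeatureTable`s (named by mode).
#' @param tol_ppm mass tolerance in ppm (default 5).
#' @return list of class `CrossModeMatch`: `matches` (data.frame: mode_a,
#'   feature_a, mode_b, feature_b, ppm), `groups` (data.frame: feature_id,
#'   mode, group), `venn` (named counts per mode combination).
#' @export
cross_mode_match <- function(tables, tol_ppm = 5) {
  if (length(tables) < 2L) stop("cross-mode matching requires >= 2 tables")
  feats <- do.call(rbind, lapply(tables, function(tab) {
    data.frame(feature_id = tab$features$feature_id,
               mode = tab$mode,
               neutral = neutral_mass(tab$features$mz, polarity(tab)),
               stringsAsFactors = FALSE)
  }))
  rownames(feats) <- NULL
  n <- nrow(feats)
  ord <- order(feats$neutral)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  matches <- list()
  # sorted sweep: only nearby masses can fall within tolerance
  for (k in seq_len(n - 1L)) {
    i <- ord[k]
    for (l in (k + 1L):n) {
      j <- ord[l]
      dppm <- ppm_error(feats$neutral[j], feats$neutral[i])
      if (dppm > tol_ppm) break
      if (feats$mode[i] != feats$mode[j]) {
        matches[[length(matches) + 1L]] <- data.frame(
          mode_a = feats$mode[i], feature_a = feats$feature_id[i],
          mode_b = feats$mode[j], feature_b = feats$feature_id[j],
          ppm = dppm, stringsAsFactors = FALSE)
        parent[find(i)] <- find(j)
      }
    }
  }
  group <- vapply(seq_len(n), find, integer(1))
  feats$group <- match(group, unique(group))
  combos <- vapply(split(feats$mode, feats$group), function(ms) {
    paste(sort(unique(ms)), collapse = "+")
  }, character(1))
  venn <- table(combos)
  list_out <- list(
    matches = if (length(matches) > 0L) do.call(rbind, matches) else
      data.frame(mode_a = character(0), feature_a = character(0),
                 mode_b = character(0), feature_b = character(0),
                 ppm = numeric(0)),
    groups = feats[, c("feature_id", "mode", "group")],
    venn = setNames(as.integer(venn), names(venn))
  )
  structure(list_out, class = "CrossModeMatch")
}

#' MS2 spectral similarity
#'
#' Normalized dot product between two fragment spectra: peaks are paired
#' greedily by nearest m/z within `frag_tol_u`, intensities are square-root
#' weighted, and the cosine over the aligned vectors is returned.
#'
#' @param spec_a,spec_b two-column matrices (mz, intensity); non-empty.
#' @param frag_tol_u fragment m/z tolerance in u.
#' @return similarity score in [0, 1].
#' @export
ms2_similarity <- function(spec_a, spec_b, frag_tol_u = 0.02) {
  spec_a <- as.matrix(spec_a); spec_b <- as.matrix(spec_b)
  if (nrow(spec_a) == 0L || nrow(spec_b) == 0L) stop("empty MS2 spectrum")
  wa <- sqrt(spec_a[, 2]); wb <- sqrt(spec_b[, 2])
  # greedy nearest pairing: smallest m/z gap first, each peak used once
  gaps <- abs(outer(spec_a[, 1], spec_b[, 1], "-"))
  gaps[gaps > frag_tol_u] <- NA
  dot <- 0
  used_a <- logical(nrow(spec_a)); used_b <- logical(nrow(spec_b))
  repeat {
    if (all(is.na(gaps))) break
    k <- arrayInd(which.min(gaps), dim(gaps))
    i <- k[1]; j <- k[2]
    dot <- dot + wa[i] * wb[j]
    used_a[i] <- TRUE; used_b[j] <- TRUE
    gaps[i, ] <- NA; gaps[, j] <- NA
  }
  dot / sqrt(sum(wa^2) * sum(wb^2))
}

#' Assign an identification confidence level from evidence flags
#'
#' Levels follow the metabolomics identification-confidence convention:
#' level 1 = reference substance confirmed by both retention time and MS2;
#' level 1a = reference substance confirmed by retention time only;
#' level 2 = MS2 spectral evidence (database or reference spectrum) without
#' a reference retention-time match; putative = exact-mass match only.
#' A mass match is a prerequisite for any level.
#'
#' @param mass_match exact-mass match within tolerance (required).
#' @param ms2_db_match MS2 spectrum matches a database spectrum.
#' @param ref_rt_match retention time matches the measured reference
#'   substance.
#' @param ref_ms2_match MS2 matches the measured reference substance.
#' @return one of `"1"`, `"1a"`, `"2"`, `"putative"`.
#' @export
assign_level <- function(mass_match, ms2_db_match = FALSE,
                         ref_rt_match = FALSE, ref_ms2_match = FALSE) {
  if (!mass_match) stop("a mass match is required for any identification level")
  if (ref_rt_match && ref_ms2_match) return("1")
  if (ref_rt_match) return("1a")
  if (ms2_db_match || ref_ms2_match) return("2")
  "putative"
}

#' Annotate features against a compound reference table
#'
#' For each feature, the neutral mass (per the table's polarity) is searched
#' against the compound table within `tol_ppm`. For each hit the evidence
#' flags are evaluated: reference retention time within `rt_tol_s`, observed
#' MS2 similarity to the reference spectrum >= `ms2_threshold`, and the
#' compound's database-MS2 flag combined with an observed spectrum. Multiple
#' compounds within tolerance are all reported, ranked by absolute ppm
#' error, with an ambiguity flag.
#'
#' @param table a `FeatureTable`.
#' @param compounds a `CompoundTable`.
#' @param tol_ppm mass tolerance (default 5 ppm).
#' @param rt_tol_s retention-time tolerance in seconds (default 18 s =
#'   0.3 min).
#' @param ms2 optional named list of observed MS2 spectra keyed by feature
#'   id (two-column mz/intensity matrices).
#' @param ms2_threshold similarity score at or above which an MS2 comparison
#'   counts as a match (default 0.7).
#' @return data.frame of class `AnnotationRecord`s: feature_id, compound,
#'   adduct, ppm, mass_match, ms2_db_match, ref_rt_match, ref_ms2_match,
#'   level, ambiguous.
#' @export
annotate_features <- function(table, compounds, tol_ppm = 5, rt_tol_s = 18,
                              ms2 = NULL, ms2_threshold = 0.7) {
  stopifnot(inherits(table, "FeatureTable"), inherits(compounds, "CompoundTable"))
  pol <- polarity(table)
  adduct <- default_adduct(pol)
  neut <- neutral_mass(table$features$mz, pol)
  out <- list()
  for (i in seq_len(nrow(table$features))) {
    err <- ppm_error(neut[i], compounds$neutral_mass)
    hits <- which(abs(err) <= tol_ppm)
    if (length(hits) == 0L) next
    hits <- hits[order(abs(err[hits]))]
    fid <- table$features$feature_id[i]
    obs_ms2 <- if (!is.null(ms2)) ms2[[fid]] else NULL
    for (h in hits) {
      ref_rt_match <- !is.na(compounds$ref_rt[h]) &&
        abs(table$features$rt[i] - compounds$ref_rt[h]) <= rt_tol_s
      ref_sp <- compounds$ms2[[h]]
      ref_ms2_match <- !is.null(obs_ms2) && !is.null(ref_sp) &&
        ms2_similarity(obs_ms2, ref_sp) >= ms2_threshold
      ms2_db_match <- !is.null(obs_ms2) && isTRUE(compounds$has_db_ms2[h])
      out[[length(out) + 1L]] <- data.frame(
        feature_id = fid,
        compound = compounds$name[h],
        adduct = adduct,
        ppm = err[h],
        mass_match = TRUE,
        ms2_db_match = ms2_db_match,
        ref_rt_match = ref_rt_match,
        ref_ms2_match = ref_ms2_match,
        level = assign_level(TRUE, ms2_db_match, ref_rt_match, ref_ms2_match),
        ambiguous = length(hits) > 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(feature_id = character(0), compound = character(0),
                      adduct = character(0), ppm = numeric(0),
                      mass_match = logical(0), ms2_db_match = logical(0),
                      ref_rt_match = logical(0), ref_ms2_match = logical(0),
                      level = character(0), ambiguous = logical(0)))
  }
  do.call(rbind, out)
}
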