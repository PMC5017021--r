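#' Construct a feature table
#'
#' The unit container of the pipeline: detected LC-MS features (m/z,
#' retention time) by injections (peak areas). One table per dataset,
#' i.e. per combination of chromatographic separation (RP or HILIC) and
#' electrospray polarity (pos or neg).
#'
#' @param features data.frame with columns `feature_id` (unique character),
#'   `mz` (positive, u) and `rt` (seconds, >= 0).
#' @param intensities numeric matrix of non-negative peak areas, one row per
#'   feature (rownames = feature ids) and one column per injection.
#' @param mode dataset label, e.g. `"RP_pos"`; must end in `_pos` or `_neg`.
#' @return An object of class `FeatureTable`.
#' @export
feature_table <- function(features, intensities, mode) {
  stopifnot(is.data.frame(features), is.matrix(intensities))
  req <- c("feature_id", "mz", "rt")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols) > 0L) {
    stop("feature table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  features$feature_id <- as.character(features$feature_id)
  dup <- features$feature_id[duplicated(features$feature_id)]
  if (length(dup) > 0L) {
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(!is.finite(features$mz)) || any(features$mz <= 0)) {
    stop("all m/z values must be positive and finite")
  }
  if (any(!is.finite(features$rt)) || any(features$rt < 0)) {
    stop("all retention times must be finite and >= 0")
  }
  if (nrow(intensities) != nrow(features)) {
    stop("intensity matrix and feature table row counts differ")
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and non-negative")
  }
  if (is.null(colnames(intensities))) {
    stop("intensity matrix must carry injection ids as column names")
  }
  rownames(intensities) <- features$feature_id
  if (!grepl("_(pos|neg)$", mode)) {
    stop("mode label must end in _pos or _neg: ", mode)
  }
  structure(
    list(features = features[, req], intensities = intensities, mode = mode),
    class = "FeatureTable"
  )
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat(sprintf(
    "FeatureTable [%s]: %d features x %d injections\n",
    x$mode, nrow(x$intensities), ncol(x$intensities)
  ))
  invisible(x)
}

#' @export
dim.FeatureTable <- function(x) dim(x$intensities)

#' Ionization polarity of a feature table or mode label
#'
#' @param x a `FeatureTable` or a mode label string.
#' @return `"pos"` or `"neg"`.
#' @export
polarity <- function(x) {
  mode <- if (inherits(x, "FeatureTable")) x$mode else x
  if (grepl("_pos$", mode)) "pos" else if (grepl("_neg$", mode)) "neg" else
    stop("cannot determine polarity from mode label: ", mode)
}

#' Construct sample metadata
#'
#' Describes every injection of a study: its role (analytical sample, blank,
#' or pooled QC), and for samples the condition, exposure time and biological
#' replicate.
#'
#' @param injection_id character, unique.
#' @param role one of `"sample"`, `"blank"`, `"pool"` per injection.
#' @param condition `"control"`/`"treated"` for samples, `"none"` for
#'   blanks and pools.
#' @param time_h exposure time in hours for samples, `NA` otherwise.
#' @param replicate biological replicate index for samples, `NA` otherwise.
#' @return data.frame of class `SampleMetadata`.
#' @export
sample_metadata <- function(injection_id, role, condition, time_h, replicate) {
  meta <- data.frame(
    injection_id = as.character(injection_id),
    role = as.character(role),
    condition = as.character(condition),
    time_h = as.numeric(time_h),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  validate_sample_metadata(meta)
  class(meta) <- c("SampleMetadata", "data.frame")
  meta
}

validate_sample_metadata <- function(meta) {
  req <- c("injection_id", "role", "condition", "time_h", "replicate")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols) > 0L) {
    stop("sample metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$injection_id)) stop("duplicate injection ids in metadata")
  if (!all(meta$role %in% c("sample", "blank", "pool"))) {
    stop("role must be one of sample/blank/pool")
  }
  if (!all(meta$condition %in% c("control", "treated", "none"))) {
    stop("condition must be one of control/treated/none")
  }
  smp <- meta$role == "sample"
  if (any(meta$condition[smp] == "none") || any(!is.finite(meta$time_h[smp]))) {
    stop("analytical samples need a condition and a finite time")
  }
  if (any(meta$condition[!smp] != "none")) {
    stop("blanks and pools must have condition 'none'")
  }
  invisible(meta)
}

#' Construct a cell-count table
#'
#' Mean viable cell numbers per (condition, time) group, used to normalize
#' peak areas for cell growth and death over the exposure time course.
#'
#' @param condition,time_h,mean_cells vectors of equal length; counts must be
#'   positive.
#' @return data.frame of class `CellCounts`.
#' @export
cell_counts <- function(condition, time_h, mean_cells) {
  counts <- data.frame(
    condition = as.character(condition),
    time_h = as.numeric(time_h),
    mean_cells = as.numeric(mean_cells),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(counts$mean_cells)) || any(counts$mean_cells <= 0)) {
    stop("all mean cell counts must be positive")
  }
  if (anyDuplicated(counts[, c("condition", "time_h")])) {
    stop("duplicate (condition, time) entries in cell counts")
  }
  class(counts) <- c("CellCounts", "data.frame")
  counts
}

#' Construct a compound reference table
#'
#' Reference compounds for annotation: name, neutral monoisotopic mass and
#' optional evidence sources (reference retention time, reference MS2
#' spectrum, availability of a database MS2 spectrum).
#'
#' @param name compound names (unique).
#' @param neutral_mass neutral monoisotopic masses, u (> 0).
#' @param ref_rt optional reference retention times, seconds (`NA` if the
#'   reference substance was not run).
#' @param has_db_ms2 logical, whether a database MS2 spectrum exists.
#' @param ms2 optional list of reference MS2 spectra; each a two-column
#'   matrix/data.frame (mz, relative intensity in (0, 1]).
#' @return data.frame of class `CompoundTable` (ms2 carried as a list column).
#' @export
compound_table <- function(name, neutral_mass, ref_rt = NA_real_,
                           has_db_ms2 = FALSE, ms2 = NULL) {
  n <- length(name)
  tab <- data.frame(
    name = as.character(name),
    neutral_mass = as.numeric(neutral_mass),
    ref_rt = rep_len(as.numeric(ref_rt), n),
    has_db_ms2 = rep_len(as.logical(has_db_ms2), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(tab$name)) stop("duplicate compound names")
  if (any(!is.finite(tab$neutral_mass)) || any(tab$neutral_mass <= 0)) {
    stop("neutral masses must be positive")
  }
  if (is.null(ms2)) ms2 <- vector("list", n)
  stopifnot(length(ms2) == n)
  for (sp in ms2) {
    if (!is.null(sp)) {
      sp <- as.matrix(sp)
      if (ncol(sp) != 2 || any(sp[, 2] <= 0) || any(sp[, 2] > 1)) {
        stop("MS2 relative intensities must lie in (0, 1]")
      }
    }
  }
  tab$ms2 <- I(ms2)
  class(tab) <- c("CompoundTable", "data.frame")
  tab
}
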