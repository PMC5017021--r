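#' Write / read a feature table as tab-separated text
#'
#' The canonical on-disk dialect: a `# mode: <label>` comment line, then a
#' header `feature_id  mz  rt  <injection ids...>`, then one row per feature.
#' Values round-trip at full double precision. Injection column order is
#' metadata-driven, not positional, so readers must not rely on it.
#'
#' @param table a `FeatureTable`.
#' @param path file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a `FeatureTable`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "FeatureTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# mode: ", table$mode), con)
  df <- data.frame(
    feature_id = table$features$feature_id,
    mz = format(table$features$mz, digits = 17, trim = TRUE, scientific = FALSE),
    rt = format(table$features$rt, digits = 17, trim = TRUE, scientific = FALSE),
    stringsAsFactors = FALSE
  )
  intens <- apply(table$intensities, 2, function(col) {
    format(col, digits = 17, trim = TRUE)
  })
  if (is.null(dim(intens))) intens <- matrix(intens, nrow = 1,
                                             dimnames = list(NULL, colnames(table$intensities)))
  df <- cbind(df, as.data.frame(intens, stringsAsFactors = FALSE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# mode: ", first)) {
    stop("feature table file must start with a '# mode: <label>' line: ", path)
  }
  mode <- sub("^# mode: ", "", first)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  req <- c("feature_id", "mz", "rt")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("feature table file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  inj_cols <- setdiff(names(df), req)
  if (length(inj_cols) == 0L) stop("feature table file has no injection columns")
  num <- function(x, what) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad) > 0L) {
      stop(sprintf("malformed %s in data row %d of %s", what, bad[1L], path))
    }
    out
  }
  features <- data.frame(
    feature_id = df$feature_id,
    mz = num(df$mz, "m/z"),
    rt = num(df$rt, "retention time"),
    stringsAsFactors = FALSE
  )
  intens <- vapply(inj_cols, function(cn) num(df[[cn]], paste("intensity", cn)),
                   numeric(nrow(df)))
  if (is.null(dim(intens))) intens <- matrix(intens, nrow = nrow(df),
                                             dimnames = list(NULL, inj_cols))
  colnames(intens) <- inj_cols
  feature_table(features, intens, mode)
}

#' Write / read sample metadata, cell counts and compound tables
#'
#' Plain tab-separated text with a header. Compound MS2 spectra are encoded
#' in a single `ms2` column as `mz:intensity` pairs joined by `;` (empty for
#' compounds without a reference spectrum).
#'
#' @param meta,counts,compounds the respective containers.
#' @param path file path.
#' @return the read functions return the respective container.
#' @name table_io
#' @export
write_sample_metadata <- function(meta, path) {
  validate_sample_metadata(meta)
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  sample_metadata(df$injection_id, df$role, df$condition, df$time_h,
                  df$replicate)
}

#' @rdname table_io
#' @export
write_cell_counts <- function(counts, path) {
  utils::write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_cell_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  cell_counts(df$condition, df$time_h, df$mean_cells)
}

#' @rdname table_io
#' @export
write_compound_table <- function(compounds, path) {
  stopifnot(inherits(compounds, "CompoundTable"))
  enc <- vapply(compounds$ms2, function(sp) {
    if (is.null(sp)) return("")
    sp <- as.matrix(sp)
    paste(sprintf("%.6f:%.6g", sp[, 1], sp[, 2]), collapse = ";")
  }, character(1))
  df <- data.frame(
    name = compounds$name,
    neutral_mass = format(compounds$neutral_mass, digits = 17, trim = TRUE,
                          scientific = FALSE),
    ref_rt = compounds$ref_rt,
    has_db_ms2 = compounds$has_db_ms2,
    ms2 = enc,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_compound_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  ms2 <- lapply(df$ms2, function(s) {
    if (is.na(s) || !nzchar(s)) return(NULL)
    pairs <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    m <- do.call(rbind, lapply(pairs, as.numeric))
    colnames(m) <- c("mz", "intensity")
    m
  })
  compound_table(df$name, df$neutral_mass, df$ref_rt, df$has_db_ms2, ms2)
}

#' Read a minimal mzTab-M small-molecule summary into a FeatureTable
#'
#' Accepts the SML section of an mzTab-M file: lines starting `SMH` (header)
#' and `SML` (rows), using the columns `SML_ID`, `exp_mass_to_charge`,
#' `retention_time_in_seconds` and `abundance_assay[n]`. Other columns and
#' sections are ignored.
#'
#' @param path file path.
#' @param mode dataset label to attach (mzTab-M does not carry one).
#' @return a `FeatureTable`.
#' @export
read_mztab_sml <- function(path, mode) {
  lines <- readLines(path)
  hdr <- grep("^SMH\\t", lines, value = TRUE)
  if (length(hdr) != 1L) stop("expected exactly one SMH header line")
  cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  rows <- grep("^SML\\t", lines, value = TRUE)
  if (length(rows) == 0L) stop("no SML rows found")
  cells <- lapply(rows, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  get <- function(name) {
    i <- match(name, cols)
    if (is.na(i)) stop("mzTab-M SML section lacks column: ", name)
    vapply(cells, `[`, character(1), i)
  }
  ab_cols <- grep("^abundance_assay\\[\\d+\\]$", cols, value = TRUE)
  if (length(ab_cols) == 0L) stop("no abundance_assay columns found")
  features <- data.frame(
    feature_id = get("SML_ID"),
    mz = as.numeric(get("exp_mass_to_charge")),
    rt = as.numeric(get("retention_time_in_seconds")),
    stringsAsFactors = FALSE
  )
  intens <- vapply(ab_cols, function(cn) as.numeric(get(cn)),
                   numeric(length(rows)))
  if (is.null(dim(intens))) intens <- matrix(intens, nrow = length(rows))
  colnames(intens) <- sub("^abundance_", "", ab_cols)
  feature_table(features, intens, mode)
}

#' Validate the consistency of a study's inputs
#'
#' Report-only cross-check of a feature table against metadata and cell
#' counts: orphan injections (in the table but not the metadata, or vice
#' versa), missing (condition, time) cell-count groups, and empty roles.
#' Fatal findings stop the pipeline; warnings do not.
#'
#' @param table a `FeatureTable`.
#' @param meta a `SampleMetadata`.
#' @param counts a `CellCounts` (optional; skip count checks when `NULL`).
#' @return list of class `ValidationReport` with `fatal` and `warnings`
#'   character vectors and an `ok` flag.
#' @export
validate_design <- function(table, meta, counts = NULL) {
  fatal <- character(0)
  warnings <- character(0)
  inj_tab <- colnames(table$intensities)
  inj_meta <- meta$injection_id
  for (x in setdiff(inj_tab, inj_meta)) {
    fatal <- c(fatal, sprintf("injection '%s' present in table but not metadata", x))
  }
  for (x in setdiff(inj_meta, inj_tab)) {
    fatal <- c(fatal, sprintf("injection '%s' present in metadata but not table", x))
  }
  for (r in c("sample", "blank", "pool")) {
    if (!any(meta$role == r)) {
      msg <- sprintf("no injections with role '%s'", r)
      if (r == "sample") fatal <- c(fatal, msg) else warnings <- c(warnings, msg)
    }
  }
  if (!is.null(counts)) {
    smp <- meta[meta$role == "sample", , drop = FALSE]
    groups <- unique(smp[, c("condition", "time_h")])
    key <- function(d) paste(d$condition, d$time_h, sep = "/")
    missing <- setdiff(key(groups), key(counts))
    for (k in missing) fatal <- c(fatal, sprintf("no cell count for %s", k))
  }
  structure(list(fatal = fatal, warnings = warnings,
                 ok = length(fatal) == 0L),
            class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat("ValidationReport:", if (x$ok) "OK" else "FATAL", "\n")
  for (f in x$fatal) cat("  fatal:", f, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
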