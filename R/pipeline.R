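PIPELINE_KEYS <- c("feature_tables", "metadata", "cell_counts", "compounds",
                   "is_feature_ids", "qc", "alpha", "pca", "annotation",
                   "exclude_injections", "seed", "output_dir")

#' Build / load a pipeline configuration
#'
#' A configuration is a named list (or a YAML file containing one) with the
#' keys: `feature_tables` (named list: mode -> path), `metadata`,
#' `cell_counts`, optional `compounds` (paths), optional `is_feature_ids`
#' (named list: mode -> ids), optional `qc` (overrides for [qc_config()]
#' arguments), `alpha` (default 0.05), `pca` (list: `ncomp` default 2,
#' `folds` default 7, `scaling` default "unit-variance"), `annotation`
#' (list: `tol_ppm` default 5, `rt_tol_s` default 18, `ms2_threshold`
#' default 0.7), optional `exclude_injections` (manually excluded outlier
#' injections, removed before PCA only), `seed` (default 1) and
#' `output_dir`. Unknown keys are rejected.
#'
#' @param config a named list or the path of a YAML file.
#' @return validated config list of class `PipelineConfig`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in c("feature_tables", "metadata", "cell_counts", "output_dir")) {
    if (is.null(config[[k]])) stop("config lacks required key: ", k)
  }
  defaults <- list(alpha = 0.05, seed = 1L,
                   pca = list(), annotation = list(),
                   exclude_injections = character(0))
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  pca_def <- list(ncomp = 2L, folds = 7L, scaling = "unit-variance")
  config$pca <- utils::modifyList(pca_def, config$pca)
  ann_def <- list(tol_ppm = 5, rt_tol_s = 18, ms2_threshold = 0.7)
  config$annotation <- utils::modifyList(ann_def, config$annotation)
  structure(config, class = c("PipelineConfig", "list"))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full profiling pipeline from a configuration
#'
#' Executes, per dataset mode: design validation, the QC chain
#' (noise -> blank -> internal-standard gate -> pool RSD), cell-number
#' normalization, per-timepoint moderated differential statistics with BH
#' correction, and PCA with cross-validated Q2; then cross-mode feature
#' matching over the QC-passing modes and (if a compound table is given)
#' annotation. A mode whose internal-standard gate fails is marked and
#' skipped for statistics; the remaining modes complete. All artefacts are
#' written to `output_dir` together with a manifest (package version, seed,
#' parameters) that fully determines the outputs of the deterministic
#' stages.
#'
#' @param config a `PipelineConfig`, bare list, or YAML path
#'   (see [pipeline_config()]).
#' @return list of class `PipelineReport`: per-mode results (`qc`, `diff`,
#'   `counts_table`, `pca`), `cross_mode`, `annotation`, `failed_modes`, and
#'   `artifacts` (named file paths).
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  set.seed(config$seed)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  meta <- read_sample_metadata(config$metadata)
  counts <- read_cell_counts(config$cell_counts)
  compounds <- if (!is.null(config$compounds)) read_compound_table(config$compounds)
  cfg <- do.call(qc_config, if (is.null(config$qc)) list() else config$qc)

  modes <- names(config$feature_tables)
  per_mode <- list()
  failed <- character(0)
  sig_counts <- list()
  filter_stages <- list()
  pca_summary <- list()

  for (mode in modes) {
    table <- read_feature_table(config$feature_tables[[mode]])
    val <- validate_design(table, meta, counts)
    if (!val$ok) {
      stop("[validate:", mode, "] ", paste(val$fatal, collapse = "; "))
    }
    is_ids <- config$is_feature_ids[[mode]]
    qc <- apply_qc(table, meta, counts, is_ids, cfg)
    filter_stages[[mode]] <- cbind(mode = mode, qc$report$stages)
    if (!qc$usable) {
      failed <- c(failed, mode)
      per_mode[[mode]] <- list(qc = qc, diff = NULL, pca = NULL)
      next
    }
    diff <- run_differential(qc$table, meta)
    cnt <- count_significant(diff, config$alpha)
    sig_counts[[mode]] <- cbind(mode = mode, cnt)

    # PCA on analytical samples (rows) x features, log2 scale
    logtab <- log_transform(qc$table)
    smp_ids <- setdiff(meta$injection_id[meta$role == "sample"],
                       config$exclude_injections)
    X <- t(logtab$intensities[, smp_ids, drop = FALSE])
    ncomp <- min(config$pca$ncomp, nrow(X) - 2L, ncol(X))
    pca <- fit_pca(X, ncomp, scaling = config$pca$scaling)
    q2 <- q2_crossval(X, ncomp, folds = config$pca$folds,
                      scaling = config$pca$scaling, seed = config$seed)
    pca_summary[[mode]] <- data.frame(
      mode = mode, ncomp = ncomp,
      r2cum = pca$r2cum[ncomp], q2cum = q2$q2cum)
    per_mode[[mode]] <- list(qc = qc, diff = diff, counts_table = cnt,
                             pca = list(model = pca, q2 = q2, samples = smp_ids))
  }

  usable_modes <- setdiff(modes, failed)
  cross <- if (length(usable_modes) >= 2L) {
    cross_mode_match(lapply(per_mode[usable_modes], function(m) m$qc$table),
                     tol_ppm = config$annotation$tol_ppm)
  }
  annotation <- NULL
  if (!is.null(compounds)) {
    annotation <- do.call(rbind, lapply(usable_modes, function(mode) {
      ann <- annotate_features(per_mode[[mode]]$qc$table, compounds,
                               tol_ppm = config$annotation$tol_ppm,
                               rt_tol_s = config$annotation$rt_tol_s,
                               ms2_threshold = config$annotation$ms2_threshold)
      if (nrow(ann) > 0L) cbind(mode = mode, ann) else NULL
    }))
  }

  out <- config$output_dir
  artifacts <- c(
    filter_report = write_tsv(do.call(rbind, filter_stages),
                              file.path(out, "filter_report.tsv")),
    significant_counts = write_tsv(
      if (length(sig_counts) > 0L) do.call(rbind, sig_counts) else
        data.frame(mode = character(0), time_h = numeric(0),
                   n_significant = integer(0)),
      file.path(out, "significant_counts.tsv"))
  )
  diff_all <- do.call(rbind, lapply(usable_modes, function(mode) {
    cbind(mode = mode, per_mode[[mode]]$diff$results)
  }))
  artifacts["differential_results"] <- write_tsv(
    if (is.null(diff_all)) data.frame() else diff_all,
    file.path(out, "differential_results.tsv"))

  artifacts["score_plots"] <- plot_scores_pdf(per_mode, usable_modes, meta,
                                              file.path(out, "score_plots.pdf"))
  artifacts["heatmap"] <- plot_heatmap_pdf(per_mode, usable_modes, config$alpha,
                                           file.path(out, "heatmap.pdf"))
  artifacts["annotation"] <- write_tsv(
    if (is.null(annotation)) data.frame(feature_id = character(0),
                                        compound = character(0)) else annotation,
    file.path(out, "annotation_table.tsv"))
  if (!is.null(cross)) {
    artifacts["cross_mode_venn"] <- write_tsv(
      data.frame(modes = names(cross$venn), n_mass_groups = cross$venn),
      file.path(out, "cross_mode_venn.tsv"))
  }

  manifest <- list(
    package = "toxmetab",
    version = as.character(utils::packageVersion("toxmetab")),
    seed = config$seed,
    alpha = config$alpha,
    qc = unclass(cfg),
    pca = config$pca,
    annotation = config$annotation,
    modes = modes,
    failed_modes = failed,
    pca_summary = if (length(pca_summary) > 0L) do.call(rbind, pca_summary)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  artifacts["manifest"] <- file.path(out, "manifest.json")

  structure(list(per_mode = per_mode, cross_mode = cross,
                 annotation = annotation, failed_modes = failed,
                 artifacts = artifacts, config = config),
            class = "PipelineReport")
}

plot_scores_pdf <- function(per_mode, modes, meta, path) {
  grDevices::pdf(path, width = 7, height = 7)
  on.exit(grDevices::dev.off())
  for (mode in modes) {
    p <- per_mode[[mode]]$pca
    if (is.null(p) || p$model$ncomp < 2L) next
    sc <- p$model$scores
    ids <- p$samples
    cond <- meta$condition[match(ids, meta$injection_id)]
    col <- ifelse(cond == "treated", "firebrick", "steelblue")
    graphics::plot(sc[, 1], sc[, 2], col = col, pch = 19,
                   xlab = "PC1", ylab = "PC2",
                   main = sprintf("%s  R2cum=%.3f Q2cum=%.3f", mode,
                                  p$model$r2cum[p$model$ncomp], p$q2$q2cum))
    graphics::text(sc[, 1], sc[, 2], labels = ids, cex = 0.5, pos = 3)
    graphics::legend("topright", legend = c("control", "treated"),
                     col = c("steelblue", "firebrick"), pch = 19, cex = 0.8)
  }
  path
}

plot_heatmap_pdf <- function(per_mode, modes, alpha, path) {
  grDevices::pdf(path, width = 7, height = 9)
  on.exit(grDevices::dev.off())
  for (mode in modes) {
    d <- per_mode[[mode]]$diff
    if (is.null(d)) next
    df <- d$results
    sig <- unique(df$feature_id[df$q < alpha])
    if (length(sig) < 2L) next
    tp <- sort(unique(df$time_h))
    m <- sapply(tp, function(t) {
      df$log2fc[df$time_h == t][match(sig, df$feature_id[df$time_h == t])]
    })
    rownames(m) <- sig
    colnames(m) <- paste0(tp, "h")
    tree <- cluster_metabolites(m)
    m <- m[tree$order, , drop = FALSE]
    pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
    lim <- max(abs(m))
    graphics::image(t(m), col = pal, zlim = c(-lim, lim), axes = FALSE,
                    main = sprintf("%s: log2FC of %d significant features",
                                   mode, nrow(m)))
    graphics::axis(1, at = seq(0, 1, length.out = ncol(m)), labels = colnames(m))
  }
  path
}
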