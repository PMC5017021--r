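#' Log2 fold change between group means
#'
#' @param treated_mean,control_mean positive group means on the raw scale.
#' @return log2(treated / control).
#' @export
log2fc <- function(treated_mean, control_mean) {
  if (any(treated_mean == 0 & control_mean == 0)) {
    stop("log2 fold change undefined when both means are zero")
  }
  log2(treated_mean / control_mean)
}

#' Log2-transform a feature table
#'
#' Peak areas are modelled on the log2 scale. Zeros are replaced by a small
#' pseudo-area before taking logs; by default half the smallest nonzero
#' intensity in the table.
#'
#' @param table a `FeatureTable`.
#' @param pseudo replacement for zero intensities; `NULL` uses half the
#'   smallest nonzero value.
#' @return the table with log2 intensities.
#' @export
log_transform <- function(table, pseudo = NULL) {
  X <- table$intensities
  if (is.null(pseudo)) {
    nz <- X[X > 0]
    if (length(nz) == 0L) stop("table is all zero; cannot log-transform")
    pseudo <- min(nz) / 2
  }
  X[X == 0] <- pseudo
  out <- table
  out$intensities <- log2(X)
  out
}

#' Invert the trigamma function
#'
#' Newton iteration on 1/trigamma, which is nearly linear; used by the
#' empirical-Bayes moment-matching estimator of the prior degrees of
#' freedom.
#'
#' @param x positive values.
#' @return y with trigamma(y) = x; `Inf` where x is 0 or smaller than
#'   trigamma can reach.
#' @keywords internal
trigamma_inverse <- function(x) {
  y <- rep(NA_real_, length(x))
  y[x > 1e7] <- 1 / sqrt(x[x > 1e7])
  y[x < 1e-6] <- 1 / x[x < 1e-6]
  todo <- is.na(y)
  if (any(todo)) {
    z <- 0.5 + 1 / x[todo]
    for (i in 1:50) {
      tri <- trigamma(z)
      dif <- tri * (1 - tri / x[todo]) / psigamma(z, 2)
      z <- z + dif
      if (max(-dif / z) < 1e-8) break
    }
    y[todo] <- z
  }
  y
}

#' Estimate empirical-Bayes moderation hyperparameters
#'
#' Moment-matching of the per-feature residual variances s2 (each on d
#' degrees of freedom) to a scaled F distribution, giving the prior degrees
#' of freedom d0 and prior variance s0^2: on the log scale,
#' e = log(s2) - digamma(d/2) + log(d/2) has variance trigamma(d/2) +
#' trigamma(d0/2) and mean log(s0^2) + digamma(d0/2) - log(d0/2). When the
#' empirical variance of e does not exceed trigamma(d/2) (no excess
#' between-feature variability), d0 is infinite and s0^2 is the mean of the
#' variances.
#'
#' @param s2 per-feature residual variances (>= 2 values).
#' @param d residual degrees of freedom (common to all features).
#' @return list of class `ModerationParams` with `d0` and `s0_sq`.
#' @export
estimate_moderation <- function(s2, d) {
  if (length(s2) < 2L) stop("moderation requires variances from >= 2 features")
  if (all(s2 == 0)) stop("all residual variances are zero; moment matching degenerate")
  ok <- s2 > 0
  e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
  e_bar <- mean(e)
  excess <- mean((e - e_bar)^2) * length(e) / (length(e) - 1) - trigamma(d / 2)
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess variability between features: common-variance limit
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ModerationParams")
}

#' Moderated two-group differential test at one time point
#'
#' Pairwise control-versus-treated comparison at a single exposure time:
#' per-feature group means on the log2 scale, pooled residual variance s2
#' with d = n1 + n2 - 2 degrees of freedom, empirical-Bayes shrinkage of s2
#' toward the prior s0^2 with weight d0 (posterior variance
#' (d0 s0^2 + d s2) / (d0 + d)), moderated t on d0 + d degrees of freedom,
#' two-sided p, and Benjamini-Hochberg q across features.
#'
#' @param table a `FeatureTable` of log2 intensities (see [log_transform()]).
#' @param meta matching `SampleMetadata`.
#' @param time_h the exposure time to test.
#' @param moderation optionally force `ModerationParams` (e.g. `d0 = 0` for
#'   the classical pooled t, `d0 = Inf` for a common variance); `NULL`
#'   estimates them from the data.
#' @return list of class `DifferentialFit`: `results` data.frame
#'   (feature_id, time_h, log2fc, s2, s2_post, t, df, p, q) and `moderation`.
#' @export
fit_moderated <- function(table, meta, time_h, moderation = NULL) {
  smp <- meta$role == "sample" & meta$time_h == time_h
  trt <- meta$injection_id[smp & meta$condition == "treated"]
  ctl <- meta$injection_id[smp & meta$condition == "control"]
  n1 <- length(trt); n2 <- length(ctl)
  if (n1 < 2L || n2 < 2L) {
    stop("need >= 2 replicates per group at time ", time_h, " h")
  }
  X <- table$intensities
  Xt <- X[, trt, drop = FALSE]
  Xc <- X[, ctl, drop = FALSE]
  m_t <- rowMeans(Xt)
  m_c <- rowMeans(Xc)
  d <- n1 + n2 - 2
  ss <- rowSums((Xt - m_t)^2) + rowSums((Xc - m_c)^2)
  s2 <- ss / d
  if (is.null(moderation)) moderation <- estimate_moderation(s2, d)
  d0 <- moderation$d0; s0_sq <- moderation$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  lfc <- m_t - m_c
  tstat <- lfc / se
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  q <- bh_adjust(p)
  results <- data.frame(
    feature_id = table$features$feature_id,
    time_h = time_h,
    log2fc = lfc,
    s2 = s2,
    s2_post = s2_post,
    t = tstat,
    df = df_total,
    p = p,
    q = q,
    stringsAsFactors = FALSE
  )
  structure(list(results = results, moderation = moderation),
            class = "DifferentialFit")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Differential analysis across the full time course
#'
#' Runs [fit_moderated()] separately at every requested time point (on a
#' log2-transformed copy of the table) and binds the per-timepoint results.
#'
#' @param table a `FeatureTable` of normalized raw-scale intensities.
#' @param meta matching `SampleMetadata`.
#' @param time_points_h times to test; defaults to all sample times
#'   with both conditions present.
#' @param pseudo passed to [log_transform()].
#' @return list of class `DifferentialResult`: `results` (stacked
#'   data.frame) and `moderation` (named list per time point).
#' @export
run_differential <- function(table, meta, time_points_h = NULL, pseudo = NULL) {
  if (is.null(time_points_h)) {
    smp <- meta[meta$role == "sample", , drop = FALSE]
    time_points_h <- sort(unique(smp$time_h))
  }
  logtab <- log_transform(table, pseudo)
  fits <- lapply(time_points_h, function(t) fit_moderated(logtab, meta, t))
  results <- do.call(rbind, lapply(fits, function(f) f$results))
  moderation <- stats::setNames(lapply(fits, function(f) f$moderation),
                                as.character(time_points_h))
  structure(list(results = results, moderation = moderation),
            class = "DifferentialResult")
}

#' Count significant features per time point
#'
#' @param results a `DifferentialResult` or its `results` data.frame.
#' @param alpha significance threshold.
#' @param on `"q"` (BH-adjusted, default) or `"p"` (raw).
#' @return data.frame with `time_h` and `n_significant`, ordered by time.
#' @export
count_significant <- function(results, alpha = 0.05, on = c("q", "p")) {
  on <- match.arg(on)
  df <- if (inherits(results, "DifferentialResult")) results$results else results
  tp <- sort(unique(df$time_h))
  n <- vapply(tp, function(t) sum(df[[on]][df$time_h == t] < alpha, na.rm = TRUE),
              integer(1))
  data.frame(time_h = tp, n_significant = n)
}
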