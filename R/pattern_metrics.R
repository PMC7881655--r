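# EMG pattern-quality metrics in the normalized feature space: within-class
# distance (consistency, lower better) and inter-class distances to the
# nearest / all other class centroids (separability, higher better), plus the
# spider-plot RMS profile used for coaching.

check_labelled <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(features) != length(labels)) stop("one label per feature vector required")
  if (nrow(features) == 0L) stop("empty feature set")
  split(seq_along(labels), labels)
}

# pluggable distance between points/centroids in feature space
metric_distance <- function(a, b, distance, inv_cov = NULL) {
  d <- a - b
  if (distance == "euclidean") sqrt(sum(d^2))
  else sqrt(drop(t(d) %*% inv_cov %*% d))
}

pooled_inv_cov <- function(features, groups, ridge = 1e-6) {
  centered <- features
  for (g in groups) {
    centered[g, ] <- sweep(features[g, , drop = FALSE], 2L,
                           colMeans(features[g, , drop = FALSE]))
  }
  S <- crossprod(centered) / max(1L, nrow(features) - length(groups))
  solve(S + diag(ridge, ncol(features)))
}

#' Within-class distance (pattern consistency)
#'
#' For each movement class, the mean distance of its feature vectors to the
#' class centroid; the summary WD is the mean over classes. Lower values mean
#' more repeatable EMG patterns. Translation-invariant by construction.
#'
#' @param features Numeric matrix of (normalized) feature vectors, one per row.
#' @param labels Movement label per row; every class must be nonempty.
#' @param distance `"euclidean"` (default) or `"mahalanobis"` (pooled
#'   within-class covariance, ridge-regularized).
#' @return List with `wd` (scalar mean over classes) and `per_class` (named
#'   numeric).
#' @export
within_class_distance <- function(features, labels,
                                  distance = c("euclidean", "mahalanobis")) {
  distance <- match.arg(distance)
  features <- as.matrix(features)
  groups <- check_labelled(features, labels)
  inv_cov <- if (distance == "mahalanobis") pooled_inv_cov(features, groups)
  per_class <- vapply(groups, function(rows) {
    centroid <- colMeans(features[rows, , drop = FALSE])
    mean(vapply(rows, function(i)
      metric_distance(features[i, ], centroid, distance, inv_cov), numeric(1)))
  }, numeric(1))
  list(wd = mean(per_class), per_class = per_class)
}

#' Inter-class distances (pattern separability)
#'
#' For each class centroid, IDNN takes the distance to the nearest other
#' centroid and IDAN the mean distance to all other centroids; both are then
#' averaged over classes. Higher values mean more separable movement
#' patterns, and IDNN never exceeds IDAN.
#'
#' @inheritParams within_class_distance
#' @return List with `idnn`, `idan` and a `per_class` data frame.
#' @export
interclass_distances <- function(features, labels,
                                 distance = c("euclidean", "mahalanobis")) {
  distance <- match.arg(distance)
  features <- as.matrix(features)
  groups <- check_labelled(features, labels)
  if (length(groups) < 2L) {
    stop("inter-class distances need at least 2 classes, got ", length(groups))
  }
  inv_cov <- if (distance == "mahalanobis") pooled_inv_cov(features, groups)
  centroids <- do.call(rbind, lapply(groups, function(rows)
    colMeans(features[rows, , drop = FALSE])))
  k <- nrow(centroids)
  D <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
    D[i, j] <- metric_distance(centroids[i, ], centroids[j, ], distance, inv_cov)
  }
  nn <- vapply(seq_len(k), function(i) min(D[i, -i]), numeric(1))
  an <- vapply(seq_len(k), function(i) mean(D[i, -i]), numeric(1))
  list(idnn = mean(nn), idan = mean(an),
       per_class = data.frame(class = rownames(centroids), nearest = nn,
                              all_mean = an, row.names = NULL))
}

#' Windows lying on the reference plateau
#'
#' Returns the analysis windows that fall entirely inside the plateau of the
#' recording's reference trace (where the reference equals its maximum). For
#' rest recordings (all-zero reference) every window qualifies.
#'
#' @param recording An [emg_recording()].
#' @param window_ms,step_ms Windowing parameters.
#' @return List of `emg_window` objects (possibly empty).
#' @export
plateau_windows <- function(recording, window_ms = 128, step_ms = 50) {
  windows <- suppressWarnings(segment_windows(recording, window_ms, step_ms))
  ref <- recording$reference
  peak <- max(ref)
  if (peak <= 0) return(windows)
  on_plateau <- ref >= peak - 1e-9
  fs <- recording$fs
  W <- as.integer(round(window_ms * fs / 1000))
  Filter(function(w) {
    s <- as.integer(round(w$start_ms * fs / 1000))
    all(on_plateau[(s + 1L):(s + W)])
  }, windows)
}

#' Session-level pattern metrics from labelled plateau features
#'
#' Computes WD, IDNN and IDAN for one recording procedure: plateau windows of
#' every graded recording are featurized, z-normalized (normalizer fitted on
#' this procedure's features), labelled by movement and fed to the metric
#' functions. Session values are means over procedures
#' ([session_metrics()]).
#'
#' @param recordings List of [emg_recording()] objects (graded trials; rest
#'   and MVC trials are ignored).
#' @param window_ms,step_ms Windowing parameters.
#' @param distance Passed to the metric functions.
#' @return List `(wd, idnn, idan, per_class_wd, per_class_id, n_windows)`.
#' @export
procedure_metrics <- function(recordings, window_ms = 128, step_ms = 50,
                              distance = c("euclidean", "mahalanobis")) {
  distance <- match.arg(distance)
  feats <- list(); labs <- character()
  for (rec in recordings) {
    if (!rec$movement %in% MOVEMENTS) next
    w <- plateau_windows(rec, window_ms, step_ms)
    if (length(w) == 0L) next
    fm <- feature_matrix(w)
    feats[[length(feats) + 1L]] <- fm
    labs <- c(labs, rep(rec$movement, nrow(fm)))
  }
  X <- do.call(rbind, feats)
  if (is.null(X) || nrow(X) < 2L) stop("no plateau windows found in the procedure")
  X <- suppressWarnings(apply_normalizer(fit_normalizer(X), X))
  wd <- within_class_distance(X, labs, distance)
  id <- interclass_distances(X, labs, distance)
  list(wd = wd$wd, idnn = id$idnn, idan = id$idan,
       per_class_wd = wd$per_class, per_class_id = id$per_class,
       n_windows = nrow(X))
}

#' @rdname procedure_metrics
#' @param procedures List of recording procedures (each with `$recordings`),
#'   e.g. from [generate_session()].
#' @return `session_metrics()`: data frame with one row per procedure plus the
#'   session mean row (`procedure = "mean"`).
#' @export
session_metrics <- function(procedures, window_ms = 128, step_ms = 50,
                            distance = c("euclidean", "mahalanobis")) {
  distance <- match.arg(distance)
  rows <- lapply(seq_along(procedures), function(i) {
    m <- procedure_metrics(procedures[[i]]$recordings, window_ms, step_ms,
                           distance)
    data.frame(procedure = as.character(i), wd = m$wd, idnn = m$idnn,
               idan = m$idan)
  })
  df <- do.call(rbind, rows)
  rbind(df, data.frame(procedure = "mean", wd = mean(df$wd),
                       idnn = mean(df$idnn), idan = mean(df$idan)))
}

#' Spider-plot RMS profile
#'
#' The per-movement, per-channel mean RMS over plateau windows — the
#' simplified feature-space picture shown to the coach as a spider plot, where
#' overlap between movement shapes flags poorly separated patterns.
#'
#' @param recordings List of [emg_recording()] objects (at least one per
#'   movement of interest; rest recordings are profiled too).
#' @param window_ms,step_ms Windowing parameters.
#' @return Data frame with columns `movement, ch1..ch8`.
#' @export
spider_profile <- function(recordings, window_ms = 128, step_ms = 50) {
  movements <- unique(vapply(recordings, function(r) r$movement, character(1)))
  rows <- lapply(movements, function(mv) {
    recs <- Filter(function(r) r$movement == mv, recordings)
    rms <- lapply(recs, function(r) {
      w <- plateau_windows(r, window_ms, step_ms)
      if (length(w) == 0L) return(NULL)
      t(vapply(w, channel_rms, numeric(8)))
    })
    rms <- do.call(rbind, rms)
    if (is.null(rms)) {
      stop("movement '", mv, "' has no plateau windows to profile")
    }
    prof <- colMeans(rms)
    stats::setNames(data.frame(mv, t(prof)), c("movement", paste0("ch", 1:8)))
  })
  do.call(rbind, rows)
}
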