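#' ROI timeseries container
#'
#' @param data T x N numeric matrix (timepoints x ROIs).
#' @param tr_seconds repetition time in seconds.
#' @param roi_names ROI labels (defaults to colnames or ROI1..ROIN).
#' @param subject_id,condition optional identifiers.
#' @param volumes_discarded count of initial volumes already removed.
#' @return object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, tr_seconds, roi_names = NULL,
                           subject_id = NA_character_,
                           condition = NA_character_,
                           volumes_discarded = 0L) {
  data <- as.matrix(data)
  if (is.null(roi_names)) {
    roi_names <- colnames(data) %||% paste0("ROI", seq_len(ncol(data)))
  }
  stopifnot(length(roi_names) == ncol(data), tr_seconds > 0,
            all(is.finite(data)))
  colnames(data) <- roi_names
  structure(
    list(data = data, tr_seconds = tr_seconds, roi_names = roi_names,
         subject_id = subject_id, condition = condition,
         volumes_discarded = as.integer(volumes_discarded)),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %s/%s: %d volumes x %d ROIs, TR %gs (%d discarded)\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data),
              x$tr_seconds, x$volumes_discarded))
  invisible(x)
}

#' Motion trace container
#'
#' Six rigid-body realignment parameters per volume: translations x, y, z
#' in mm then rotations pitch, roll, yaw in radians (rp-file convention).
#'
#' @param params T x 6 numeric matrix.
#' @param tr_seconds repetition time in seconds.
#' @export
motion_trace <- function(params, tr_seconds) {
  params <- as.matrix(params)
  stopifnot(ncol(params) == 6, nrow(params) >= 2)
  if (!all(is.finite(params))) {
    bad <- which(!apply(params, 1, function(r) all(is.finite(r))))[1]
    stop("non-finite motion parameters at frame ", bad)
  }
  colnames(params) <- c("trans_x", "trans_y", "trans_z",
                        "rot_pitch", "rot_roll", "rot_yaw")
  structure(list(params = params, tr_seconds = tr_seconds),
            class = "motion_trace")
}

#' Framewise displacement (FD)
#'
#' Per-frame head-motion summary: the sum of absolute backward differences
#' of the six realignment parameters, with the three rotations first
#' converted from radians to millimetres of arc on a sphere of
#' `head_radius` (Power convention, 50 mm).
#'
#' @param motion a [motion_trace()].
#' @param head_radius sphere radius in mm used to convert rotations.
#' @return list with `fd_series` (length T-1, mm) and `mean_fd` (mm),
#'   class `motion_summary`.
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  stopifnot(inherits(motion, "motion_trace"))
  p <- motion$params
  d <- abs(diff(p))
  d[, 4:6] <- d[, 4:6] * head_radius
  fd <- rowSums(d)
  structure(list(fd_series = fd, mean_fd = mean(fd)),
            class = "motion_summary")
}

#' Apply the motion inclusion rule
#'
#' A subject is kept only if mean FD is strictly below `threshold` in every
#' condition (exactly-at-threshold counts as exclusion).
#'
#' @param summaries named list: `summaries[[subject]][[condition]]` is a
#'   `motion_summary` (or a bare mean-FD number).
#' @param threshold mm, default 0.5.
#' @return list with character vectors `kept` and `excluded`.
#' @export
apply_inclusion_rule <- function(summaries, threshold = 0.5) {
  conds <- unique(unlist(lapply(summaries, names)))
  kept <- excluded <- character(0)
  for (s in names(summaries)) {
    have <- names(summaries[[s]])
    if (!setequal(have, conds)) {
      stop("subject ", s, " is missing condition(s): ",
           paste(setdiff(conds, have), collapse = ", "))
    }
    fds <- vapply(summaries[[s]], function(x) {
      if (inherits(x, "motion_summary")) x$mean_fd else as.numeric(x)
    }, numeric(1))
    if (all(fds < threshold)) kept <- c(kept, s) else excluded <- c(excluded, s)
  }
  list(kept = kept, excluded = excluded)
}

#' Discard initial volumes (steady-state magnetisation)
#' @param ts a `roi_timeseries`.
#' @param n number of leading volumes to drop (default 10).
#' @export
discard_initial_volumes <- function(ts, n = 10) {
  stopifnot(inherits(ts, "roi_timeseries"), n >= 0)
  if (nrow(ts$data) <= n) {
    stop("cannot discard ", n, " volumes from a ", nrow(ts$data),
         "-volume series")
  }
  if (n == 0) return(ts)
  ts$data <- ts$data[-seq_len(n), , drop = FALSE]
  ts$volumes_discarded <- ts$volumes_discarded + as.integer(n)
  ts
}

#' Nuisance regression and detrending
#'
#' Replaces each ROI series with the residual of an ordinary least-squares
#' fit on an intercept, an optional linear trend, and any supplied nuisance
#' regressors (motion parameters, white-matter / CSF signals).  Residuals
#' are orthogonal to every design column.
#'
#' @param ts a `roi_timeseries`.
#' @param regressors optional T x P matrix of nuisance regressors.
#' @param detrend include a linear trend column (default TRUE).
#' @export
regress_nuisance <- function(ts, regressors = NULL, detrend = TRUE) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n <- nrow(ts$data)
  X <- matrix(1, n, 1)
  cn <- "intercept"
  if (detrend) {
    X <- cbind(X, seq_len(n) - (n + 1) / 2)
    cn <- c(cn, "trend")
  }
  if (!is.null(regressors)) {
    regressors <- as.matrix(regressors)
    stopifnot(nrow(regressors) == n)
    X <- cbind(X, regressors)
    cn <- c(cn, colnames(regressors) %||%
              paste0("reg", seq_len(ncol(regressors))))
  }
  colnames(X) <- cn
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- cn[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient nuisance design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  ts$data <- qr.resid(qrX, ts$data)
  colnames(ts$data) <- ts$roi_names
  ts
}

# Butterworth band-pass coefficients for a given TR
bandpass_coefs <- function(tr_seconds, low_hz, high_hz, order = 2) {
  nyq <- 1 / (2 * tr_seconds)
  if (low_hz <= 0 || high_hz >= nyq || low_hz >= high_hz) {
    stop(sprintf("band [%g, %g] Hz outside (0, Nyquist = %g) or inverted",
                 low_hz, high_hz, nyq))
  }
  signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
}

# zero-phase filtering with reflective padding to tame edge transients
filtfilt_padded <- function(filt, x) {
  n <- length(x)
  np <- min(n - 1, 100)
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- signal::filtfilt(filt, xp)
  y[(np + 1):(np + n)]
}

#' Band-pass filter ROI timeseries
#'
#' Zero-phase (forward-backward) Butterworth band-pass restricted to the
#' low-frequency band used for resting-state connectivity, applied per ROI
#' column.  DC and drift are removed together with high-frequency
#' physiological noise.
#'
#' @param ts a `roi_timeseries`.
#' @param low_hz,high_hz passband edges in Hz (defaults 0.01 and 0.09).
#' @param order Butterworth prototype order (default 2).
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.09, order = 2) {
  stopifnot(inherits(ts, "roi_timeseries"))
  bf <- bandpass_coefs(ts$tr_seconds, low_hz, high_hz, order)
  ts$data <- apply(ts$data, 2, function(col) filtfilt_padded(bf, col))
  colnames(ts$data) <- ts$roi_names
  ts
}

#' Average voxel signals into ROI mean timeseries
#'
#' @param voxel_data T x V matrix of voxel signals.
#' @param labels length-V assignment of voxels to ROI labels.
#' @param tr_seconds repetition time.
#' @export
extract_roi_means <- function(voxel_data, labels, tr_seconds = 2) {
  voxel_data <- as.matrix(voxel_data)
  stopifnot(length(labels) == ncol(voxel_data))
  rois <- unique(labels)
  counts <- table(labels)
  if (any(counts < 1)) stop("empty ROI")
  out <- vapply(rois, function(r) {
    rowMeans(voxel_data[, labels == r, drop = FALSE])
  }, numeric(nrow(voxel_data)))
  roi_timeseries(out, tr_seconds = tr_seconds, roi_names = as.character(rois))
}

#' Global signal fluctuation (GSF)
#'
#' Temporal standard deviation of the across-ROI mean signal; used as a
#' per-subject confound summary.
#'
#' @param ts a `roi_timeseries`.
#' @export
global_signal_fluctuation <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"), nrow(ts$data) >= 2)
  stats::sd(rowMeans(ts$data))
}

#' Full timeseries-level preprocessing for one run
#'
#' discard leading volumes -> nuisance regression (+ detrend) ->
#' band-pass, in that order.
#'
#' @param ts a `roi_timeseries` (raw, including leading volumes).
#' @param motion optional [motion_trace()]; its 6 parameters (after the
#'   same discard) are used as nuisance regressors.
#' @param discard leading volumes to drop.
#' @param low_hz,high_hz passband.
#' @param extra_regressors optional additional columns (rows must match the
#'   series after discarding).
#' @return preprocessed `roi_timeseries`.
#' @export
preprocess_run <- function(ts, motion = NULL, discard = 10,
                           low_hz = 0.01, high_hz = 0.09,
                           extra_regressors = NULL) {
  ts <- discard_initial_volumes(ts, discard)
  reg <- NULL
  if (!is.null(motion)) {
    reg <- motion$params[-seq_len(discard), , drop = FALSE]
    reg <- sweep(reg, 2, colMeans(reg))
    # drop parameter columns with no motion at all (constant -> collinear
    # with the intercept)
    reg <- reg[, apply(reg, 2, function(c) stats::sd(c) > 0), drop = FALSE]
    if (ncol(reg) == 0) reg <- NULL
  }
  if (!is.null(extra_regressors)) reg <- cbind(reg, extra_regressors)
  ts <- regress_nuisance(ts, regressors = reg, detrend = TRUE)
  bandpass(ts, low_hz, high_hz)
}
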