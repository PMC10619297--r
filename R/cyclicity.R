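# Cyclic/acyclic classification: autocorrelation profiles of nightly
# temperature, DTW distances, hierarchical clustering, and cluster labelling
# with an individual-level override.

#' Autocorrelation profile of a nightly temperature signal
#'
#' Computes the standard (biased) autocorrelation estimate of one
#' participant's nightly series at lags `0..max_lag` days. The series is
#' placed on a complete daily grid first; missing nights are linearly
#' interpolated. More than 20% missing nights, or any missing run longer
#' than 14 nights, disqualifies the participant.
#'
#' @param nightly One participant's nightly summaries (data.frame with
#'   `date` and the chosen signal column), or a plain numeric vector of
#'   nightly values.
#' @param signal Which nightly aggregate to use: the temperature trend
#'   deviation (default) or the nightly temperature maximum.
#' @param max_lag Maximum lag in days (default 90, about three cycles in six
#'   months of data); capped at one less than the series length.
#' @param min_nights Minimum number of nightly values required (default 60).
#' @return An object of class `acf_profile`: list(pid, lags, acf,
#'   source_signal).
#' @export
compute_acf <- function(nightly, signal = c("temp_trend_dev", "temp_max"),
                        max_lag = 90, min_nights = 60) {
  signal <- match.arg(signal)
  if (is.numeric(nightly)) {
    y <- nightly
    pid <- NA_character_
  } else {
    dt <- data.table::as.data.table(nightly)
    stopifnot(all(c("date", signal) %in% names(dt)))
    pid <- if ("pid" %in% names(dt)) dt$pid[1] else NA_character_
    if (nrow(dt) < min_nights)
      stop(sprintf("insufficient data: %d nights (< %d required)",
                   nrow(dt), min_nights), call. = FALSE)
    y <- fill_daily_gaps(dt$date, dt[[signal]])$values
  }
  if (length(y) < min_nights)
    stop(sprintf("insufficient data: %d nights (< %d required)",
                 length(y), min_nights), call. = FALSE)
  max_lag <- min(max_lag, length(y) - 1L)
  a <- stats::acf(y, lag.max = max_lag, plot = FALSE, demean = TRUE)
  structure(list(pid = pid, lags = 0:max_lag, acf = as.numeric(a$acf),
                 source_signal = signal),
            class = "acf_profile")
}

#' Autocorrelation profiles for a cohort
#'
#' Applies [compute_acf()] per participant; participants whose series are
#' disqualified (too short, too gappy) are skipped and reported in the
#' `disqualified` attribute.
#'
#' @param nightly Cohort nightly summaries (multiple pids).
#' @inheritParams compute_acf
#' @return Named list of `acf_profile`s with attribute `disqualified`.
#' @export
acf_profiles <- function(nightly, signal = c("temp_trend_dev", "temp_max"),
                         max_lag = 90, min_nights = 60) {
  signal <- match.arg(signal)
  dt <- data.table::as.data.table(nightly)
  ids <- unique(dt$pid)
  out <- list(); bad <- character()
  for (id in ids) {
    pr <- tryCatch(compute_acf(dt[pid == id], signal, max_lag, min_nights),
                   error = function(e) NULL)
    if (is.null(pr)) bad <- c(bad, id) else out[[id]] <- pr
  }
  if (length(bad))
    warning(sprintf("%d participant(s) disqualified from ACF: %s",
                    length(bad), paste(bad, collapse = ", ")), call. = FALSE)
  attr(out, "disqualified") <- bad
  out
}

profile_values <- function(x) {
  if (inherits(x, "acf_profile")) x$acf else as.numeric(x)
}

#' Dynamic-time-warping distance between two profiles
#'
#' Exact DTW by full dynamic programming with absolute-difference local
#' cost and no warping-window constraint. Symmetric, and zero exactly when
#' the two profiles are identical.
#'
#' @param a,b `acf_profile`s on the same lag grid, or numeric vectors.
#' @return Non-negative distance.
#' @export
dtw_distance <- function(a, b) {
  if (inherits(a, "acf_profile") && inherits(b, "acf_profile") &&
      !identical(a$lags, b$lags))
    stop("validation error: profiles are on different lag grids", call. = FALSE)
  .dtw_cost(profile_values(a), profile_values(b))
}

#' Pairwise DTW distance matrix
#'
#' @param profiles List of `acf_profile`s (equal lag grids) or numeric
#'   vectors.
#' @return Symmetric matrix with zero diagonal, dimnames from pids where
#'   available.
#' @export
dtw_distance_matrix <- function(profiles) {
  vals <- lapply(profiles, profile_values)
  grids <- lapply(profiles, function(p) if (inherits(p, "acf_profile")) p$lags)
  grids <- Filter(Negate(is.null), grids)
  if (length(grids) > 1 && !all(vapply(grids, identical, logical(1), grids[[1]])))
    stop("validation error: profiles are on different lag grids", call. = FALSE)
  d <- .dtw_pairwise(vals)
  ids <- names(profiles) %||%
    vapply(profiles, function(p) if (inherits(p, "acf_profile")) p$pid else NA_character_,
           character(1))
  if (!anyNA(ids)) dimnames(d) <- list(ids, ids)
  d
}

#' Agglomerative clustering of a precomputed distance matrix
#'
#' @param dist Symmetric distance matrix with zero diagonal (e.g. from
#'   [dtw_distance_matrix()]).
#' @param k Number of clusters to cut (default 3).
#' @param linkage Agglomeration method passed to [stats::hclust()]:
#'   `"average"` (default), `"single"`, `"complete"`, or `"ward.D2"`.
#' @return Integer cluster ids named by the matrix dimnames.
#' @export
cluster_profiles <- function(dist, k = 3,
                             linkage = c("average", "single", "complete",
                                         "ward.D2")) {
  linkage <- match.arg(linkage)
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist) || any(abs(dist - t(dist)) > 1e-8) ||
      any(diag(dist) != 0))
    stop("validation error: dist must be symmetric with zero diagonal",
         call. = FALSE)
  if (k > nrow(dist))
    stop_config("k", "exceeds the number of profiles")
  hc <- stats::hclust(stats::as.dist(dist), method = linkage)
  stats::cutree(hc, k = k)
}

# Highest local maximum of an ACF profile within the candidate period band.
# Returns NULL when no interior local maximum reaches into the band.
acf_peak <- function(profile, band = c(20, 32)) {
  v <- profile_values(profile)
  lags <- if (inherits(profile, "acf_profile")) profile$lags
  lags <- lags %||% (seq_along(v) - 1L)
  i <- which(lags >= band[1] & lags <= band[2])
  i <- i[i > 1 & i < length(v)]
  loc <- i[v[i] > v[i - 1] & v[i] >= v[i + 1]]
  if (!length(loc)) return(NULL)
  best <- loc[which.max(v[loc])]
  list(period = lags[best], value = v[best])
}

#' Label clusters as cyclic or acyclic
#'
#' A cluster is cyclic when its mean autocorrelation profile has a local
#' maximum of at least `theta` within the 20--32-day lag band. Members of a
#' cyclic cluster whose own profile lacks such a peak are relabelled
#' acyclic with `override_applied = TRUE` -- automating the manual
#' reassignment of lone non-cyclic members that clustering can place in a
#' cyclic cluster.
#'
#' @param clusters Integer cluster ids named by pid (see
#'   [cluster_profiles()]).
#' @param profiles Named list of `acf_profile`s matching `clusters`.
#' @param theta Peak threshold in ACF units (default 0.3, above the
#'   white-noise ACF ceiling of about 0.25 for 180-night series and far
#'   below the peak of a genuine monthly cycle).
#' @param band Candidate period band in days (default `c(20, 32)`).
#' @return data.table: pid, cluster_id, label, override_applied,
#'   peak_period_days, peak_acf.
#' @export
assign_labels <- function(clusters, profiles, theta = 0.3, band = c(20, 32)) {
  stopifnot(length(clusters) == length(profiles))
  ids <- names(clusters) %||% names(profiles) %||%
    as.character(seq_along(profiles))
  if (!is.null(names(profiles))) profiles <- profiles[ids]
  cyclic_cluster <- vapply(sort(unique(clusters)), function(cl) {
    mean_prof <- rowMeans(vapply(profiles[clusters == cl], profile_values,
                                 numeric(length(profile_values(profiles[[1]])))))
    pk <- acf_peak(structure(list(lags = profiles[[1]]$lags, acf = mean_prof),
                             class = "acf_profile"), band)
    !is.null(pk) && pk$value >= theta
  }, logical(1))
  names(cyclic_cluster) <- sort(unique(clusters))
  out <- data.table::rbindlist(lapply(seq_along(ids), function(i) {
    cl <- clusters[[i]]
    pk <- acf_peak(profiles[[i]], band)
    has_peak <- !is.null(pk) && pk$value >= theta
    label <- if (cyclic_cluster[[as.character(cl)]]) "cyclic" else "acyclic"
    override <- FALSE
    if (label == "cyclic" && !has_peak) {
      label <- "acyclic"; override <- TRUE
    }
    data.table::data.table(
      pid = ids[i], cluster_id = cl, label = label,
      override_applied = override,
      peak_period_days = if (label == "cyclic") pk$period else NA_real_,
      peak_acf = if (label == "cyclic") pk$value else NA_real_)
  }))
  out[]
}

#' Classify a cohort as cyclic or acyclic from nightly summaries
#'
#' End-to-end wrapper: autocorrelation profiles, pairwise DTW distances,
#' agglomerative clustering cut at `k`, and cluster labelling with the
#' individual override.
#'
#' @param nightly Cohort nightly summaries.
#' @inheritParams acf_profiles
#' @inheritParams cluster_profiles
#' @inheritParams assign_labels
#' @return data.table of per-participant results (see [assign_labels()]),
#'   with the profiles and distance matrix attached as attributes
#'   `profiles` and `dist`.
#' @export
classify_cyclicity <- function(nightly,
                               signal = c("temp_trend_dev", "temp_max"),
                               max_lag = 90, min_nights = 60, k = 3,
                               linkage = "average", theta = 0.3,
                               band = c(20, 32)) {
  signal <- match.arg(signal)
  profiles <- acf_profiles(nightly, signal, max_lag, min_nights)
  d <- dtw_distance_matrix(profiles)
  cl <- cluster_profiles(d, k = min(k, length(profiles)), linkage = linkage)
  res <- assign_labels(cl, profiles, theta = theta, band = band)
  attr(res, "profiles") <- profiles
  attr(res, "dist") <- d
  res
}
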