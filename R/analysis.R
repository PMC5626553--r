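#' Track-level summary metrics
#'
#' Condenses a per-frame metrics table into one row of track
#' descriptors: maximum and mean corrected length, straightness at
#' maximum length, median tip extension / retraction and base
#' invasion / retraction rates (movement partitioned at the
#' +/-\code{state_threshold_nm_s} threshold), tip persistence, state
#' time fractions, initial tip/base movement (median over the first
#' \code{initial_window_points} time points) and fluorescence
#' summaries. Movement series are percentile-filtered and smoothed
#' first. A track is flagged as a newly formed filopodium when its
#' first frame is after frame 1 and its starting length is below
#' \code{new_filo_max_start_length_um}.
#'
#' @param metrics Data frame from \code{\link{track_metrics}}.
#' @param aparams An \code{\link{analysis_params}}.
#' @param frame_interval_s Frame interval in seconds.
#' @param preformation_fluor Optional pre-formation fluorescence
#'   summary (from \code{\link{predicted_base_fluorescence}}).
#' @return One-row data frame of class \code{track_summary}.
#' @export
summarize_track <- function(metrics, aparams = analysis_params(),
                            frame_interval_s = 2,
                            preformation_fluor = NA_real_) {
  thr <- aparams$state_threshold_nm_s
  dctm_s <- preprocess_series(metrics$dctm_nm_s, aparams)
  dcbm_s <- preprocess_series(metrics$dcbm_nm_s, aparams)
  st <- classify_states(dctm_s, dcbm_s, aparams, frame_interval_s)
  pers <- tip_persistence(dctm_s, aparams, frame_interval_s)
  med_if <- function(x, cond) {
    v <- x[!is.na(x) & cond(x)]
    if (length(v)) median(v) else NA_real_
  }
  len <- metrics$length_um
  imax <- if (all(is.na(len))) NA_integer_ else which.max(len)
  head_n <- aparams$initial_window_points
  first_len <- len[!is.na(len)][1]
  new_filo <- metrics$frame[1] > 1L &&
    !is.na(first_len) && first_len < aparams$new_filo_max_start_length_um
  data.frame(
    track_id = metrics$track_id[1],
    n_frames = nrow(metrics),
    start_frame = metrics$frame[1],
    new_filopodium = new_filo,
    max_length_um = if (is.na(imax)) NA_real_ else len[imax],
    mean_length_um = mean(len, na.rm = TRUE),
    straightness_at_max = if (is.na(imax)) NA_real_
      else metrics$straightness[imax],
    median_tip_extension_rate = med_if(dctm_s, function(x) x > thr),
    median_tip_retraction_rate = med_if(dctm_s, function(x) x < -thr),
    median_base_invasion_rate = med_if(dcbm_s, function(x) x > thr),
    median_base_retraction_rate = med_if(dcbm_s, function(x) x < -thr),
    tip_persistence_s = pers$persistence_s,
    persistence_censored = pers$censored,
    frac_extending = st$frac_extending,
    frac_retracting = st$frac_retracting,
    frac_stalling = st$frac_stalling,
    frac_base_invading = st$frac_base_invading,
    frac_base_retracting = st$frac_base_retracting,
    frac_base_stable = st$frac_base_stable,
    initial_tip_movement = median(head(dctm_s, head_n), na.rm = TRUE),
    initial_base_movement = median(head(dcbm_s, head_n), na.rm = TRUE),
    preformation_fluor = preformation_fluor,
    mean_tip_fluor = if ("normalized_tip" %in% names(metrics))
      mean(metrics$normalized_tip, na.rm = TRUE) else NA_real_,
    mean_body_fluor = if ("body_mean" %in% names(metrics))
      mean(metrics$body_mean, na.rm = TRUE) else NA_real_
  )
}

#' Spearman correlation matrix with Holm adjustment
#'
#' Pairwise-complete Spearman correlations between track summary
#' columns, with Holm-adjusted p-values over all unique off-diagonal
#' tests. Constant (or all-NA) columns give NA correlations.
#'
#' @param summaries Data frame (e.g. rbind of
#'   \code{\link{summarize_track}} rows); only numeric columns are
#'   used.
#' @param alpha Significance level recorded in the result.
#' @return List with matrices \code{rho}, \code{p_raw}, \code{p_adj},
#'   logical \code{significant}, and \code{alpha}.
#' @export
correlation_matrix <- function(summaries, alpha = 0.05) {
  num <- summaries[vapply(summaries, is.numeric, TRUE)]
  num <- num[, !(names(num) %in% c("track_id", "start_frame", "n_frames")),
             drop = FALSE]
  p <- ncol(num)
  if (nrow(num) < 4) stop("need at least 4 tracks", call. = FALSE)
  rho <- matrix(NA_real_, p, p, dimnames = list(names(num), names(num)))
  praw <- rho
  diag(rho) <- 1
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    ok <- complete.cases(num[[i]], num[[j]])
    if (sum(ok) < 4 || sd(num[[i]][ok]) == 0 || sd(num[[j]][ok]) == 0) next
    ct <- suppressWarnings(
      cor.test(num[[i]][ok], num[[j]][ok], method = "spearman",
               exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    praw[i, j] <- praw[j, i] <- ct$p.value
  }
  up <- upper.tri(praw)
  padj <- praw
  padj[up] <- p.adjust(praw[up], method = "holm")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  list(rho = rho, p_raw = praw, p_adj = padj,
       significant = !is.na(padj) & padj < alpha, alpha = alpha)
}

# Sample cross-correlation at lags -max_lag..max_lag, classical
# convention: overall means and sds, denominator n. Value at lag k is
# the correlation of x_{t+k} with y_t, so with x = fluorescence and
# y = movement, negative lags mean fluorescence precedes movement.
# NA pairs are dropped and the remaining sum rescaled to the biased
# estimator; with complete series this equals stats::ccf.
cross_correlation <- function(x, y, max_lag) {
  n <- length(x)
  stopifnot(length(y) == n)
  mx <- mean(x, na.rm = TRUE); my <- mean(y, na.rm = TRUE)
  sx <- sqrt(mean((x - mx)^2, na.rm = TRUE))
  sy <- sqrt(mean((y - my)^2, na.rm = TRUE))
  lags <- -max_lag:max_lag
  vals <- vapply(lags, function(k) {
    if (k >= 0) { xi <- (1 + k):n; yi <- 1:(n - k) }
    else { xi <- 1:(n + k); yi <- (1 - k):n }
    px <- x[xi] - mx; py <- y[yi] - my
    ok <- !is.na(px) & !is.na(py)
    if (!any(ok)) return(NA_real_)
    sum(px[ok] * py[ok]) * ((n - abs(k)) / sum(ok)) / (n * sx * sy)
  }, 0)
  list(lags = lags, values = vals)
}

#' Cross-correlation between tip fluorescence and tip movement
#'
#' Computes the sample cross-correlation function between a normalized
#' tip fluorescence series and the (percentile-filtered, smoothed)
#' DCTM series over a symmetric lag window. Negative offsets mean
#' fluorescence precedes movement. Tracks with fewer than
#' \code{min_series_points_ccf} paired time points are excluded.
#'
#' @param norm_tip_fluor,dctm Numeric series (already preprocessed).
#' @param max_lag_s Half-width of the lag window, seconds.
#' @param frame_interval_s Frame interval, seconds.
#' @param aparams An \code{\link{analysis_params}}.
#' @param track_id Optional identifier carried in the profile.
#' @return A \code{ccf_profile}: list with \code{track_id},
#'   \code{lags_s}, \code{ccf}, \code{valid}, \code{reason}.
#' @export
ccf_fluorescence_movement <- function(norm_tip_fluor, dctm,
                                      max_lag_s = 20,
                                      frame_interval_s = 2,
                                      aparams = analysis_params(),
                                      track_id = NA_integer_) {
  n_pairs <- sum(!is.na(norm_tip_fluor) & !is.na(dctm))
  if (n_pairs < aparams$min_series_points_ccf) {
    return(structure(list(track_id = track_id, lags_s = numeric(0),
                          ccf = numeric(0), valid = FALSE,
                          reason = sprintf(
                            "only %d paired points (minimum %d)",
                            n_pairs, aparams$min_series_points_ccf)),
                     class = "ccf_profile"))
  }
  max_lag <- max(1L, round(max_lag_s / frame_interval_s))
  max_lag <- min(max_lag, length(dctm) - 1L)
  cc <- cross_correlation(norm_tip_fluor, dctm, max_lag)
  structure(list(track_id = track_id,
                 lags_s = cc$lags * frame_interval_s,
                 ccf = cc$values, valid = TRUE, reason = NA_character_),
            class = "ccf_profile")
}

profiles_to_matrix <- function(profiles, offset_range_s) {
  profiles <- Filter(function(p) isTRUE(p$valid), profiles)
  if (length(profiles) < 2) stop("need at least 2 valid profiles",
                                 call. = FALSE)
  lags <- profiles[[1]]$lags_s
  sel <- lags >= offset_range_s[1] & lags <= offset_range_s[2]
  m <- t(vapply(profiles, function(p) p$ccf[sel], numeric(sum(sel))))
  rownames(m) <- vapply(profiles, function(p) as.character(p$track_id), "")
  colnames(m) <- lags[sel]
  attr(m, "lags_s") <- lags[sel]
  m
}

#' Hierarchical clustering of CCF profiles
#'
#' Clusters tracks by the Euclidean distance between their CCF values
#' at offsets within \code{offset_range_s} (default -6..+6 s). The
#' "responding" subcluster is the cluster with the highest mean CCF at
#' offset 0 under the chosen cut. The cut (number of clusters or a
#' height) is an explicit parameter: the choice of threshold is a
#' judgement call, not an output of the method.
#'
#' @param profiles List of \code{ccf_profile} (invalid ones are
#'   dropped).
#' @param offset_range_s Length-2 numeric: lag window in seconds.
#' @param k Number of clusters (ignored if \code{h} is given).
#' @param h Optional cut height.
#' @param linkage Agglomeration method for \code{\link[stats]{hclust}}.
#' @return List with \code{labels} (named by track id),
#'   \code{responding_cluster}, \code{lag0_cluster_means},
#'   \code{hclust}, \code{matrix}.
#' @export
cluster_ccfs <- function(profiles, offset_range_s = c(-6, 6), k = 2,
                         h = NULL, linkage = "complete") {
  m <- profiles_to_matrix(profiles, offset_range_s)
  hc <- hclust(dist(m), method = linkage)
  labels <- if (is.null(h)) cutree(hc, k = k) else cutree(hc, h = h)
  lag0 <- which.min(abs(attr(m, "lags_s")))
  means <- tapply(m[, lag0], labels, mean)
  responding <- as.integer(names(means)[which.max(means)])
  list(labels = labels, responding_cluster = responding,
       lag0_cluster_means = means, hclust = hc, matrix = m)
}

#' Shuffle a series in blocks, preserving within-block order
#'
#' Splits the series into consecutive blocks of \code{block} points
#' (the last block may be shorter) and permutes the block order. This
#' preserves short-range autocorrelation within blocks while breaking
#' the alignment with any other series. A series no longer than one
#' block is returned unchanged.
#'
#' @param x Numeric series.
#' @param block Block length in time points.
#' @return Shuffled series of the same length and multiset of values.
#' @export
block_shuffle <- function(x, block = 8L) {
  n <- length(x)
  nb <- ceiling(n / block)
  if (nb <= 1L) return(x)
  idx <- split(seq_len(n), rep(seq_len(nb), each = block)[seq_len(n)])
  unlist(lapply(idx[sample.int(nb)], function(i) x[i]), use.names = FALSE)
}

#' Block-randomization significance test for the responding subcluster
#'
#' Null model for the fluorescence-movement coupling seen in the
#' responding subcluster: each track's smoothed DCTM series is
#' reshuffled in blocks of \code{block} time points (preserving its
#' autocorrelation), CCFs are recomputed, the profiles are reclustered
#' identically, and the randomization is accepted only when the
#' top-correlating subcluster has a size within \code{size_tol} of the
#' real one. The test statistic is the mean CCF at offset 0 over the
#' responding subcluster; the p-value is the fraction of accepted
#' randomizations whose statistic reaches the observed one (reported
#' as < 1/n_accepted when none do).
#'
#' @param fluor_list,dctm_list Lists of (preprocessed) series, one
#'   pair per track.
#' @param block Block length.
#' @param n_accepted Number of accepted randomizations required.
#' @param size_tol Relative subcluster-size acceptance tolerance.
#' @param seed Integer seed.
#' @param k,offset_range_s,linkage Passed to \code{\link{cluster_ccfs}}.
#' @param max_lag_s,frame_interval_s,aparams Passed to
#'   \code{\link{ccf_fluorescence_movement}}.
#' @param max_attempts Attempt cap; if fewer than 1\% of attempts are
#'   accepted the test aborts with diagnostics.
#' @return List with \code{observed}, \code{p_value},
#'   \code{p_reported}, \code{null_stats}, \code{n_accepted},
#'   \code{n_attempted}, \code{real_subcluster_size}, \code{seed}.
#' @export
block_randomization_test <- function(fluor_list, dctm_list, block = 8L,
                                     n_accepted = 1000L, size_tol = 0.15,
                                     seed = 1L, k = 2,
                                     offset_range_s = c(-6, 6),
                                     linkage = "complete",
                                     max_lag_s = 20,
                                     frame_interval_s = 2,
                                     aparams = analysis_params(),
                                     max_attempts = 100L * n_accepted) {
  stopifnot(length(fluor_list) == length(dctm_list))
  # tracks below the paired-point minimum are excluded, as in the
  # real-data CCF analysis
  ok <- vapply(seq_along(fluor_list), function(i)
    sum(!is.na(fluor_list[[i]]) & !is.na(dctm_list[[i]])) >=
      aparams$min_series_points_ccf, TRUE)
  fluor_list <- fluor_list[ok]
  dctm_list <- dctm_list[ok]
  if (length(fluor_list) < 2) {
    stop("fewer than 2 tracks with enough paired points", call. = FALSE)
  }
  # CCFs only at the lags the clustering uses
  max_lag <- max(1L, round(max(abs(offset_range_s)) / frame_interval_s))
  lags_s <- (-max_lag:max_lag) * frame_interval_s
  sel <- lags_s >= offset_range_s[1] & lags_s <= offset_range_s[2]
  lag0 <- which(lags_s[sel] == 0)
  ccf_mat <- function(dctms) {
    t(vapply(seq_along(dctms), function(i)
      cross_correlation(fluor_list[[i]], dctms[[i]], max_lag)$values[sel],
      numeric(sum(sel))))
  }
  stat_of <- function(m) {
    hc <- hclust(dist(m), method = linkage)
    labels <- cutree(hc, k = k)
    means <- tapply(m[, lag0], labels, mean)
    top <- as.integer(names(means)[which.max(means)])
    list(size = sum(labels == top), stat = max(means))
  }
  real <- stat_of(ccf_mat(dctm_list))
  real_size <- real$size
  observed <- real$stat
  set.seed(seed)
  null_stats <- numeric(0)
  attempts <- 0L
  while (length(null_stats) < n_accepted && attempts < max_attempts) {
    attempts <- attempts + 1L
    shuffled <- lapply(dctm_list, block_shuffle, block = block)
    s <- stat_of(ccf_mat(shuffled))
    if (abs(s$size - real_size) > size_tol * real_size) next
    null_stats <- c(null_stats, s$stat)
    if (attempts >= 500L && length(null_stats) / attempts < 0.01) {
      stop("block randomization: acceptance rate ",
           signif(length(null_stats) / attempts, 2), " after ", attempts,
           " attempts (real subcluster size ", real_size,
           "); check size_tol and k", call. = FALSE)
    }
  }
  n_acc <- length(null_stats)
  if (n_acc < n_accepted) {
    stop("block randomization: only ", n_acc, " accepted in ", attempts,
         " attempts", call. = FALSE)
  }
  n_ge <- sum(null_stats >= observed)
  p <- n_ge / n_acc
  list(observed = observed, p_value = p,
       p_reported = if (n_ge == 0) sprintf("<%g", 1 / n_acc)
         else sprintf("%g", p),
       null_stats = null_stats, n_accepted = n_acc,
       n_attempted = attempts, real_subcluster_size = real_size,
       seed = seed)
}

#' Fit a discrete-time Markov chain to a series
#'
#' Bins the series into \code{n_bins} equal-width intervals over its
#' observed range and estimates the transition matrix from observed
#' state-to-state counts. The model is invalid when the range is
#' degenerate (constant series) or when any visited state has no
#' outgoing observation, which makes a row of the matrix undefined.
#'
#' @param x Numeric series (NAs dropped).
#' @param n_bins Number of states.
#' @return A \code{markov_model}: list with \code{bin_edges},
#'   \code{midpoints}, \code{transition_matrix}, \code{initial_state},
#'   \code{states}, \code{valid}, \code{reason}.
#' @export
markov_fit <- function(x, n_bins = 9L) {
  x <- x[!is.na(x)]
  invalid <- function(reason)
    structure(list(bin_edges = NULL, midpoints = NULL,
                   transition_matrix = NULL, initial_state = NA_integer_,
                   states = integer(0), valid = FALSE, reason = reason),
              class = "markov_model")
  if (length(x) < 2) return(invalid("series too short"))
  rng <- range(x)
  if (diff(rng) == 0) {
    return(invalid("degenerate range (constant series): single occupied state"))
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  states <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
                 n_bins)
  from <- states[-length(states)]
  to <- states[-1L]
  counts <- matrix(0, n_bins, n_bins)
  for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  visited <- sort(unique(states))
  no_out <- visited[rowSums(counts)[visited] == 0]
  if (length(no_out)) {
    return(invalid(paste0("state(s) ", paste(no_out, collapse = ","),
                          " visited but with no outgoing observation")))
  }
  P <- counts / rowSums(counts)
  P[is.nan(P)] <- 0  # never-visited rows: unused by simulation
  structure(list(bin_edges = edges,
                 midpoints = (edges[-1] + edges[-length(edges)]) / 2,
                 transition_matrix = P,
                 initial_state = states[1L],
                 states = states, valid = TRUE, reason = NA_character_),
            class = "markov_model")
}

#' Simulate realizations of a fitted Markov chain
#'
#' Simulates \code{n_sim} independent state sequences of length
#' \code{n_steps}, all starting from the model's initial state, and
#' returns them as bin-midpoint values.
#'
#' @param model A valid \code{\link{markov_fit}} model.
#' @param n_steps Sequence length.
#' @param n_sim Number of realizations.
#' @return \code{n_steps} x \code{n_sim} numeric matrix of midpoint
#'   values.
#' @export
markov_simulate <- function(model, n_steps, n_sim = 1L) {
  stopifnot(isTRUE(model$valid), n_steps >= 1)
  P <- model$transition_matrix
  cumP <- t(apply(P, 1, cumsum))
  s <- matrix(0L, n_steps, n_sim)
  s[1L, ] <- model$initial_state
  for (t in seq_len(n_steps - 1L)) {
    u <- runif(n_sim)
    s[t + 1L, ] <- 1L + rowSums(cumP[s[t, ], , drop = FALSE] <
                                  u)  # inverse-CDF draw per chain
  }
  matrix(model$midpoints[s], n_steps, n_sim)
}

#' Markov-chain null test for fluorescence-movement correlation
#'
#' Fits independent Markov chains to the binned fluorescence and
#' movement series of one track, simulates \code{n_sim} realization
#' pairs from the two chains, and compares the observed correlation of
#' the binned series against the null distribution of simulated
#' correlations. Tracks with an invalid transition matrix are
#' discarded with a reason.
#'
#' @param norm_tip_fluor,dctm Numeric series.
#' @param n_sim Number of simulation pairs.
#' @param n_bins Number of Markov states per variable.
#' @param seed Integer seed.
#' @return List with \code{valid}, \code{reason}, \code{observed},
#'   \code{null_corr} (length \code{n_sim}), \code{p_value},
#'   \code{z_score}, \code{n_exceeding}, \code{seed}.
#' @export
markov_null_test <- function(norm_tip_fluor, dctm, n_sim = 10000L,
                             n_bins = 9L, seed = 1L) {
  ok <- !is.na(norm_tip_fluor) & !is.na(dctm)
  f <- norm_tip_fluor[ok]; m <- dctm[ok]
  mf <- markov_fit(f, n_bins)
  mm <- markov_fit(m, n_bins)
  if (!mf$valid || !mm$valid) {
    reason <- paste(c(if (!mf$valid) paste("fluorescence:", mf$reason),
                      if (!mm$valid) paste("movement:", mm$reason)),
                    collapse = "; ")
    return(list(valid = FALSE, reason = reason, observed = NA_real_,
                null_corr = numeric(0), p_value = NA_real_,
                z_score = NA_real_, n_exceeding = NA_integer_,
                seed = seed))
  }
  n <- length(f)
  observed <- cor(mf$midpoints[mf$states], mm$midpoints[mm$states])
  set.seed(seed)
  sim_f <- markov_simulate(mf, n, n_sim)
  sim_m <- markov_simulate(mm, n, n_sim)
  null_corr <- vapply(seq_len(n_sim), function(i) {
    sf <- sim_f[, i]; sm <- sim_m[, i]
    if (sd(sf) == 0 || sd(sm) == 0) 0 else cor(sf, sm)
  }, 0)
  n_ge <- sum(null_corr >= observed)
  list(valid = TRUE, reason = NA_character_, observed = observed,
       null_corr = null_corr, p_value = n_ge / n_sim,
       z_score = (observed - mean(null_corr)) / sd(null_corr),
       n_exceeding = n_ge, seed = seed)
}
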