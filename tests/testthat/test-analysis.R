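# track summaries, correlation mining, CCF, clustering, randomization

test_that("constant-extension track summarizes as fully extending", {
  n <- 40
  metrics <- data.frame(track_id = 1L, frame = 2:(n + 1),
                        time_s = (1:n) * 2,
                        length_um = 1 + (1:n) * 0.1,
                        dL_um = 0.1,
                        dctm_nm_s = rep(50, n), dcbm_nm_s = rep(0, n),
                        straightness = 1, waviness = 0)
  s <- summarize_track(metrics, analysis_params(), 2)
  expect_equal(s$median_tip_extension_rate, 50)
  expect_equal(s$frac_extending, 1)
  expect_equal(s$frac_stalling, 0)
  expect_true(is.na(s$median_tip_retraction_rate))
  expect_equal(s$max_length_um, 1 + n * 0.1)
  expect_true(s$new_filopodium)  # starts after frame 1, short start
})

test_that("new-filopodium gate needs formation after frame 1", {
  metrics <- data.frame(track_id = 1L, frame = 1:20, time_s = 0:19 * 2,
                        length_um = 1, dL_um = 0, dctm_nm_s = 0,
                        dcbm_nm_s = 0, straightness = 1, waviness = 0)
  s <- summarize_track(metrics, analysis_params(), 2)
  expect_false(s$new_filopodium)
  # long at first appearance: not new either
  metrics2 <- metrics
  metrics2$frame <- 2:21
  metrics2$length_um <- 3
  expect_false(summarize_track(metrics2, analysis_params(), 2)$new_filopodium)
})

test_that("initial tip movement is the median of the first 10 points", {
  vals <- seq(10, 100, by = 10)
  # later points bracket the initial window so the percentile filter
  # leaves the first ten values untouched
  metrics <- data.frame(track_id = 1L, frame = 2:21, time_s = 1:20 * 2,
                        length_um = 1, dL_um = 0,
                        dctm_nm_s = c(vals, 5, 105, rep(50, 8)),
                        dcbm_nm_s = 0, straightness = 1, waviness = 0)
  ap <- analysis_params(rolling_window = 1L)  # no smoothing: exact arithmetic
  s <- summarize_track(metrics, ap, 2)
  expect_equal(s$initial_tip_movement, 55)
})

test_that("Spearman matrix matches rank-based oracle and Holm adjustment", {
  set.seed(20)
  n <- 24
  a <- rnorm(n)
  df <- data.frame(track_id = 1:n,
                   a = a, b = a^3,  # strictly monotone in a
                   c = rnorm(n), d = rnorm(n))
  cm <- correlation_matrix(df)
  expect_equal(cm$rho["a", "b"], 1, tolerance = 1e-9)
  # oracle: Pearson on ranks
  expect_equal(cm$rho["a", "c"], cor(rank(a), rank(df$c)),
               tolerance = 1e-12)
  expect_true(isSymmetric(cm$rho))
  expect_true(all(diag(cm$rho) == 1))
  # Holm definition on a known p triple
  expect_equal(p.adjust(c(0.001, 0.01, 0.04), "holm"),
               c(0.003, 0.02, 0.04))
  # adjusted >= raw, monotone in raw order
  up <- upper.tri(cm$p_adj)
  expect_true(all(cm$p_adj[up] >= cm$p_raw[up], na.rm = TRUE))
  o <- order(cm$p_raw[up])
  expect_true(!is.unsorted(cm$p_adj[up][o], na.rm = TRUE))
})

test_that("constant columns are flagged as undefined, others computed", {
  df <- data.frame(track_id = 1:10, a = rnorm(10), b = rep(2, 10),
                   c = rnorm(10))
  cm <- correlation_matrix(df)
  expect_true(is.na(cm$rho["a", "b"]))
  expect_false(is.na(cm$rho["a", "c"]))
})

test_that("CCF of a series with itself is 1 at lag zero", {
  set.seed(6)
  x <- rnorm(60)
  p <- ccf_fluorescence_movement(x, x, max_lag_s = 10)
  expect_equal(p$ccf[p$lags_s == 0], 1, tolerance = 1e-9)
})

test_that("CCF matches stats::ccf on complete series", {
  set.seed(61)
  x <- rnorm(80); y <- rnorm(80)
  p <- ccf_fluorescence_movement(x, y, max_lag_s = 12, frame_interval_s = 2)
  ref <- ccf(x, y, lag.max = 6, plot = FALSE)
  expect_equal(p$ccf, as.numeric(ref$acf), tolerance = 1e-9)
})

test_that("a lagged copy peaks where fluorescence leads", {
  set.seed(62)
  m <- as.numeric(arima.sim(list(ar = 0.5), 120))
  f <- c(m[3:120], rnorm(2, 0, 1e-6))  # fluorescence leads by 2 frames
  p <- ccf_fluorescence_movement(f, m, max_lag_s = 12, frame_interval_s = 2)
  expect_equal(p$lags_s[which.max(p$ccf)], -4)  # 2 frames * 2 s, leading
})

test_that("series below 17 paired points are excluded with a reason", {
  p <- ccf_fluorescence_movement(rnorm(16), rnorm(16))
  expect_false(p$valid)
  expect_match(p$reason, "16 paired")
  # NAs count against pairing
  x <- rnorm(30); x[1:20] <- NA
  p2 <- ccf_fluorescence_movement(x, rnorm(30))
  expect_false(p2$valid)
})

test_that("null white-noise pairs rarely reach |CCF(0)| = 0.3", {
  hits <- 0
  for (i in 1:100) {
    cs <- generate_coupled_series(100, coupling = 0, ar_coeff = 0,
                                  seed = 400 + i)
    p <- ccf_fluorescence_movement(cs$fluorescence, cs$movement,
                                   max_lag_s = 4)
    if (abs(p$ccf[p$lags_s == 0]) < 0.3) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("clustering separates responding from flat CCF templates", {
  set.seed(77)
  mk_profile <- function(id, peak) {
    lags <- seq(-10, 10)
    v <- peak * exp(-lags^2 / 4) + rnorm(21, 0, 0.03)
    structure(list(track_id = id, lags_s = lags * 2, ccf = v,
                   valid = TRUE, reason = NA), class = "ccf_profile")
  }
  profs <- c(lapply(1:6, mk_profile, peak = 0.7),
             lapply(7:14, mk_profile, peak = 0))
  cl <- cluster_ccfs(profs, k = 2)
  labs <- cl$labels
  expect_equal(length(unique(labs[as.character(1:6)])), 1)
  expect_equal(length(unique(labs[as.character(7:14)])), 1)
  expect_true(all(labs[as.character(1:6)] == cl$responding_cluster))
  # identical profiles merge at distance zero
  two <- list(mk_profile(1, 0.5), mk_profile(1, 0.5))
  two[[2]]$ccf <- two[[1]]$ccf
  two[[2]]$track_id <- 2
  cl2 <- cluster_ccfs(two, k = 1)
  expect_equal(cl2$hclust$height[1], 0)
})

test_that("the lag-window restriction changes the distances", {
  set.seed(78)
  mk <- function(id) {
    lags <- seq(-10, 10)
    v <- rnorm(21, 0, 0.2)
    structure(list(track_id = id, lags_s = lags * 2, ccf = v,
                   valid = TRUE, reason = NA), class = "ccf_profile")
  }
  profs <- lapply(1:5, mk)
  m_narrow <- filotrack:::profiles_to_matrix(profs, c(-6, 6))
  m_wide <- filotrack:::profiles_to_matrix(profs, c(-20, 20))
  expect_equal(ncol(m_narrow), 7)   # -6,-4,-2,0,2,4,6 at 2 s
  expect_gt(ncol(m_wide), ncol(m_narrow))
  expect_false(isTRUE(all.equal(as.numeric(dist(m_narrow)),
                                as.numeric(dist(m_wide)))))
})

test_that("block shuffle preserves values, blocks, and short series", {
  x <- seq_len(20) * 1.0
  set.seed(30)
  y <- block_shuffle(x, 8)
  expect_setequal(y, x)
  # within-block order preserved: each shuffled block appears contiguously
  blocks <- list(1:8, 9:16, 17:20)
  starts <- vapply(blocks, function(b) which(y == x[b[1]])[1], 0L)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    expect_equal(y[starts[i] + seq_along(b) - 1], x[b])
  }
  expect_identical(block_shuffle(x[1:8], 8), x[1:8])  # single block
})

test_that("block randomization detects strong coupling", {
  d <- coupled_dataset(14, 56, coupling = 0.8, seed0 = 900)
  r <- block_randomization_test(d$fluor, d$dctm, n_accepted = 199L,
                                seed = 2)
  expect_lt(r$p_value, 0.01)
  expect_match(r$p_reported, "^<")
  expect_equal(r$n_accepted, 199L)
})

test_that("randomized null statistics center near zero for decoupled data", {
  d <- coupled_dataset(14, 56, coupling = 0, seed0 = 950)
  r <- block_randomization_test(d$fluor, d$dctm, n_accepted = 199L,
                                seed = 3)
  expect_lt(abs(mean(r$null_stats)) , 0.25)
  expect_gt(r$p_value, 0.01)
})
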