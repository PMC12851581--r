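test_that("relative_uptake maps deuterons to percent of the labeling maximum", {
  expect_equal(relative_uptake(0, 5), 0)
  expect_equal(relative_uptake(0.9 * 4, 4), 100)
  expect_equal(relative_uptake(1.8, 4, labeling_fraction = 0.9), 50)
  expect_error(relative_uptake(1, 0), "n_exch")
})

test_that("welch_t_test matches the reference implementation and honors conventions", {
  # oracle: stats::t.test (Welch) over random samples
  set.seed(10)
  for (i in 1:25) {
    xs <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1), sd = runif(1, 0.1, 2))
    ys <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1), sd = runif(1, 0.1, 2))
    w <- welch_t_test(xs, ys)
    ref <- t.test(xs, ys)
    expect_equal(w$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$dof, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
    # symmetry: swapping samples negates t, preserves p
    ws <- welch_t_test(ys, xs)
    expect_equal(ws$t_stat, -w$t_stat, tolerance = 1e-12)
    expect_equal(ws$p_value, w$p_value, tolerance = 1e-12)
  }
  # identical samples with spread: t = 0, p = 1
  w0 <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t_stat, 0)
  expect_equal(w0$p_value, 1)
  # degenerate conventions
  eq <- welch_t_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(eq$p_value, 1)
  expect_true(eq$degenerate)
  ne <- welch_t_test(c(1, 1, 1), c(2, 2, 2))
  expect_equal(ne$p_value, .Machine$double.xmin)
  expect_true(ne$degenerate)
  expect_error(welch_t_test(1, c(1, 2)), ">= 2")
})

test_that("delta_uptake is antisymmetric and matches brute-force cell statistics", {
  ds <- fixture_dataset(n = 80, n_peptides = 20, states = c("apo", "mel"),
                        replicates = 3, seed = 21)
  d <- delta_uptake(ds, "mel", "apo")
  expect_s3_class(d, "hdx_differential")
  # one row per shared (peptide, timepoint)
  expect_equal(nrow(d), 20 * 3)

  # self-difference is identically zero with p = 1
  d_self <- delta_uptake(ds, "apo", "apo")
  expect_true(all(d_self$delta_d == 0))
  expect_true(all(d_self$p_value == 1))

  # antisymmetry under state swap; p unchanged
  d_rev <- delta_uptake(ds, "apo", "mel")
  key <- function(x) paste(x$sequence, x$start, x$end, x$timepoint)
  m <- match(key(d), key(d_rev))
  expect_equal(d$delta_d, -d_rev$delta_d[m], tolerance = 1e-12)
  expect_equal(d$p_value, d_rev$p_value[m], tolerance = 1e-12)

  # brute-force oracle: recompute every cell's means/SDs from raw records
  rec <- ds$records
  for (i in sample(nrow(d), 10)) {
    pick <- function(st) rec$uptake[rec$state == st &
      rec$sequence == d$sequence[i] & rec$start == d$start[i] &
      rec$end == d$end[i] & rec$timepoint == d$timepoint[i]]
    xs <- pick("mel"); ys <- pick("apo")
    expect_equal(d$delta_d[i], mean(xs) - mean(ys), tolerance = 1e-12)
    expect_equal(d$sd_holo[i], sd(xs), tolerance = 1e-12)
    expect_equal(d$sd_apo[i], sd(ys), tolerance = 1e-12)
    expect_equal(d$p_value[i], t.test(xs, ys)$p.value, tolerance = 1e-10)
  }
  expect_error(delta_uptake(ds, "nope", "apo"), "nope")
})

test_that("cells with < 2 replicates are emitted with unavailable tests, never dropped", {
  prot <- fixture_protein(20)
  peps <- data.frame(start = c(1L, 8L), end = c(6L, 13L))
  rec <- rbind(
    fixture_records(prot, peps, states = "apo", timepoints = 30,
                    replicates = 3),
    fixture_records(prot, peps[1, , drop = FALSE], states = "mel",
                    timepoints = 30, replicates = 3),
    fixture_records(prot, peps[2, , drop = FALSE], states = "mel",
                    timepoints = 30, replicates = 1))
  ds <- hdx_dataset(prot, rec)
  d <- delta_uptake(ds, "mel", "apo")
  expect_equal(nrow(d), 2L)
  one_rep <- d$start == 8
  expect_false(d$test_available[one_rep])
  expect_true(is.na(d$p_value[one_rep]))
  expect_false(is.na(d$delta_d[one_rep]))
  thr <- global_threshold(ds, "mel", "apo")
  cls <- hybrid_classify(d, thr)
  expect_false(cls$significant[one_rep])
})

test_that("global_threshold equals the closed form and scales with the noise", {
  # closed-form oracle computed independently from raw records
  ds <- fixture_dataset(n = 60, n_peptides = 8, states = c("apo", "mel"),
                        replicates = 3, seed = 31)
  thr <- global_threshold(ds, "mel", "apo", alpha = 0.05)
  rec <- ds$records
  cells <- split(rec$uptake,
                 paste(rec$sequence, rec$start, rec$end, rec$timepoint,
                       rec$state))
  ss <- sum(vapply(cells, function(v) sum((v - mean(v))^2), 0))
  dof <- sum(vapply(cells, length, 0L) - 1L)
  sp <- sqrt(ss / dof)
  expect_equal(thr$pooled_sd, sp, tolerance = 1e-12)
  expect_equal(thr$dof, dof)
  expect_equal(thr$threshold,
               qt(0.975, dof) * sp * sqrt(1 / 3 + 1 / 3), tolerance = 1e-12)

  # doubling every replicate's deviation from its cell mean doubles both
  rec2 <- rec
  keyv <- paste(rec$sequence, rec$start, rec$end, rec$timepoint, rec$state)
  cellmean <- ave(rec$uptake, keyv)
  rec2$uptake <- cellmean + 2 * (rec$uptake - cellmean)
  ds2 <- hdx_dataset(ds$protein, rec2, validate = FALSE)
  thr2 <- global_threshold(ds2, "mel", "apo")
  expect_equal(thr2$pooled_sd, 2 * thr$pooled_sd, tolerance = 1e-10)
  expect_equal(thr2$threshold, 2 * thr$threshold, tolerance = 1e-10)

  # zero-variance degenerate: threshold 0 with warning
  rec3 <- rec; rec3$uptake <- cellmean
  ds3 <- hdx_dataset(ds$protein, rec3, validate = FALSE)
  expect_warning(thr3 <- global_threshold(ds3, "mel", "apo"), "zero")
  expect_equal(thr3$threshold, 0)
})

test_that("hybrid criteria require BOTH the magnitude and the p-value arm", {
  ds <- fixture_dataset(n = 60, n_peptides = 8, states = c("apo", "mel"),
                        replicates = 3, seed = 41)
  d <- delta_uptake(ds, "mel", "apo")
  thr <- global_threshold(ds, "mel", "apo")
  cls <- hybrid_classify(d, thr)
  # conjunction rule on every record
  expect_true(all(!cls$significant |
                  (abs(cls$delta_d) > thr$threshold &
                   cls$p_value < thr$alpha)))
  expect_true(all(cls$direction[!cls$significant] == "none"))
  expect_true(all(cls$direction[cls$significant & cls$delta_d < 0] ==
                  "protected"))
  expect_true(all(cls$direction[cls$significant & cls$delta_d > 0] ==
                  "deprotected"))

  # forced corners: large |dD| with p >= alpha is NOT significant,
  # tiny |dD| with tiny p is NOT significant
  corner <- d[1:2, ]
  corner$delta_d <- c(2 * thr$threshold, thr$threshold / 2)
  corner$p_value <- c(0.2, 1e-6)
  corner$test_available <- TRUE
  class(corner) <- class(d)
  cc <- hybrid_classify(corner, thr)
  expect_false(any(cc$significant))

  # monotonicity: at fixed p < alpha, growing |dD| never turns significance off
  grid <- d[rep(1, 12), ]
  grid$p_value <- 0.01
  grid$test_available <- TRUE
  grid$delta_d <- seq(0, 4 * thr$threshold, length.out = 12)
  class(grid) <- class(d)
  sig <- hybrid_classify(grid, thr)$significant
  expect_true(all(diff(sig) >= 0))
})

test_that("residual curves sum timepoint differentials into totals", {
  ds <- fixture_dataset(n = 60, n_peptides = 8, states = c("apo", "mel"),
                        replicates = 3, seed = 51)
  d <- delta_uptake(ds, "mel", "apo")
  rc <- residual_curves(d)
  expect_equal(nrow(rc), 8L)
  # oracle: independent summation per peptide
  for (i in seq_len(nrow(rc))) {
    sel <- d$start == rc$start[i] & d$end == rc$end[i]
    expect_equal(rc$total[i], sum(d$delta_d[sel]), tolerance = 1e-12)
  }
  expect_true(all(diff(rc$start) >= 0))
  # all-zero differentials give all-zero curves
  d0 <- d; d0$delta_d <- 0
  class(d0) <- class(d)
  expect_true(all(residual_curves(d0)$total == 0))
})

test_that("optional analysis knobs: log-transform testing, BH layer, uptake scaling", {
  ds <- fixture_dataset(n = 60, n_peptides = 8, states = c("apo", "mel"),
                        replicates = 3, seed = 61)
  d_raw <- delta_uptake(ds, "mel", "apo")
  d_log <- delta_uptake(ds, "mel", "apo", log_transform = TRUE)
  expect_equal(d_log$delta_d, d_raw$delta_d)  # effect stays on raw scale
  i <- which(d_raw$test_available)[1]
  rec <- ds$records
  pick <- function(st) rec$uptake[rec$state == st &
    rec$sequence == d_raw$sequence[i] & rec$start == d_raw$start[i] &
    rec$end == d_raw$end[i] & rec$timepoint == d_raw$timepoint[i]]
  ref <- t.test(log(pmax(pick("mel"), 1e-6)), log(pmax(pick("apo"), 1e-6)))
  expect_equal(d_log$p_value[i], ref$p.value, tolerance = 1e-10)

  # BH never creates significance that unadjusted p lacked
  thr <- global_threshold(ds, "mel", "apo")
  plain <- hybrid_classify(d_raw, thr)
  bh <- hybrid_classify(d_raw, thr, p_adjust = "BH")
  expect_true(all(!bh$significant | plain$significant))

  # multiplicative uptake correction on read
  f <- tempfile(fileext = ".csv")
  write_dataset(ds, f)
  ds_scaled <- read_uptake_table(f, ds$protein, uptake_scale = 0.5)
  expect_equal(ds_scaled$records$uptake, ds$records$uptake * 0.5,
               tolerance = 1e-12)
})
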