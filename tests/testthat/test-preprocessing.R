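make_flat_panel <- function(values, rois = names(values[[1]]),
                            n = length(values[[1]][[1]])) {
  # single subject, single block panel from named column lists
  tbl <- tibble::tibble(subject_id = "s1", condition = "resting",
                        block_index = 1L, volume = seq_len(n))
  for (r in rois) tbl[[r]] <- values[[1]][[r]]
  bgcausal:::as_bg_panel(tbl, rois, 1.6)
}

test_that("confound regression is exact OLS per block", {
  n <- 200
  set.seed(1)
  cf <- sin(seq_len(n) / 30) + 0.01 * seq_len(n)
  e <- rnorm(n)
  panel <- make_flat_panel(list(list(A = cf, B = 2 * cf + e)))
  confounds <- tibble::tibble(subject_id = "s1", condition = "resting",
                              block_index = 1L, volume = seq_len(n),
                              confound = cf)
  out <- regress_confounds(panel, confounds)
  # series equal to the confound becomes exactly zero
  expect_lt(max(abs(out$A)), 1e-10)
  # residual orthogonal to the confound to machine precision
  expect_lt(abs(sum(out$B * (cf - mean(cf)))), 1e-8)
  expect_equal(dim(out), dim(panel))
  # misaligned confounds are reported with the offending block
  bad <- confounds[-5, ]
  expect_error(regress_confounds(panel, bad), "s1/resting/1")
})

test_that("high-pass projection removes drift and passes the band", {
  n <- 100
  t_sec <- (seq_len(n) - 1) * 1.6
  expect_error(highpass(make_flat_panel(list(list(A = rnorm(n)))),
                        cutoff_hz = 0), "cutoff")
  # constant series -> zero
  out <- highpass(make_flat_panel(list(list(A = rep(3, n)))))
  expect_lt(max(abs(out$A)), 1e-10)
  # 0.05 Hz sinusoid passes nearly unchanged (cosine phase: the basis's
  # natural phase; sine phase additionally loses block-edge leakage)
  s <- cos(2 * pi * 0.05 * ((seq_len(n) - 0.5) * 1.6))
  out <- highpass(make_flat_panel(list(list(A = s))))
  expect_lt(sqrt(mean((out$A - s)^2)) / sqrt(mean(s^2)), 0.05)
  # arbitrary phase matches an explicit least-squares projection oracle
  # (basis rebuilt by hand: cosines below 0.009 Hz plus constant and drift)
  s2 <- sin(2 * pi * 0.05 * t_sec + 0.7)
  out2 <- highpass(make_flat_panel(list(list(A = s2))))
  tt <- seq_len(n) - 0.5
  oracle_basis <- cbind(1, cos(pi * 1 * tt / n), cos(pi * 2 * tt / n),
                        tt - mean(tt))
  oracle <- resid(lm(s2 ~ oracle_basis))
  expect_equal(out2$A, as.numeric(oracle), tolerance = 1e-10)
  # linear ramp almost fully removed
  ramp <- seq(-1, 1, length.out = n)
  out <- highpass(make_flat_panel(list(list(A = ramp))))
  expect_lt(sqrt(mean(out$A^2)), 0.05 * sqrt(mean(ramp^2)))
})

test_that("high-pass reduces the sub-cutoff band of an injected confound", {
  g <- ground_truth_graph(c("A", "B"))
  sim <- simulate_panel(
    g, subject_spec("s1", blocks_per_condition = 1L, block_length = 400L,
                    conditions = "resting"), seed = 2)
  band_power <- function(y, tr = 1.6, cutoff = 0.009) {
    sp <- stats::spec.pgram(stats::ts(y, deltat = tr), plot = FALSE,
                            taper = 0, detrend = FALSE)
    sum(sp$spec[sp$freq < cutoff])
  }
  out <- highpass(sim$panel)
  expect_lt(band_power(out$A), 0.5 * band_power(sim$panel$A))
})

test_that("per-subject centring is exact, idempotent and shift-invariant", {
  g <- ground_truth_graph(c("A", "B"))
  sim <- simulate_panel(g, study_subjects(3), seed = 5, confound = FALSE)
  cen <- center_per_subject(sim$panel)
  means <- cen |>
    dplyr::group_by(subject_id, condition) |>
    dplyr::summarise(dplyr::across(c(A, B), mean), .groups = "drop")
  expect_lt(max(abs(c(means$A, means$B))), 1e-10)
  expect_equal(as.data.frame(center_per_subject(cen)), as.data.frame(cen))
  # adding a per-subject offset changes nothing after centring
  shifted <- sim$panel
  shifted$A <- shifted$A + ifelse(shifted$subject_id == "sub01", 5, -5)
  expect_equal(as.data.frame(center_per_subject(shifted))$A, cen$A)
  # variance preserved (no rescaling)
  expect_equal(var(cen$A), var(sim$panel$A -
    stats::ave(sim$panel$A, sim$panel$subject_id, sim$panel$condition)))
  # zscore switch rescales to unit variance
  z <- center_per_subject(sim$panel, zscore = TRUE)
  v <- z |>
    dplyr::group_by(subject_id, condition) |>
    dplyr::summarise(v = var(A), .groups = "drop")
  expect_equal(v$v, rep(1, nrow(v)), tolerance = 1e-10)
})

test_that("concatenation orders blocks, records boundaries and only touches edges", {
  g <- ground_truth_graph(c("A", "B"))
  sim <- simulate_panel(g, study_subjects(4), seed = 6, confound = FALSE)
  cc <- concatenate_blocks(sim$panel, "resting")
  expect_equal(nrow(cc), 4 * 2 * 100)
  expect_equal(attr(cc, "boundaries"), seq(1L, 800L, by = 100L))
  expect_error(concatenate_blocks(sim$panel, "nope"), "no blocks")
  # single block: interior samples (6..95) bit-identical to the input
  one <- sim$panel[sim$panel$subject_id == "sub01" &
                     sim$panel$condition == "resting" &
                     sim$panel$block_index == 1, ]
  cc1 <- concatenate_blocks(bgcausal:::as_bg_panel(one, c("A", "B"), 1.6),
                            "resting")
  expect_identical(cc1$A[6:95], one$A[6:95])
  # at most 10 samples per block per ROI change
  full <- sim$panel[sim$panel$condition == "resting", ]
  full <- full[order(full$subject_id, full$block_index, full$volume), ]
  changed <- matrix(cc$A != full$A, nrow = 100)
  expect_true(all(colSums(changed) <= 10))
})

test_that("boundary smoothing equals the direct-summation Gaussian oracle", {
  # step discontinuity at a block join: last value -1, first value +1
  n <- 40
  a1 <- c(rep(0, n - 1), -1)
  a2 <- c(1, rep(0, n - 1))
  tbl <- tibble::tibble(
    subject_id = rep(c("s1", "s2"), each = n), condition = "resting",
    block_index = 1L, volume = rep(seq_len(n), 2), A = c(a1, a2))
  panel <- bgcausal:::as_bg_panel(tbl, "A", 1.6)
  cc <- concatenate_blocks(panel, "resting")
  x <- c(a1, a2)
  w <- exp(-((-2):2)^2 / 2)
  oracle <- vapply(seq_along(x), function(t) {
    idx <- (t - 2):(t + 2)
    ok <- idx >= 1 & idx <= length(x)
    sum(w[ok] * x[idx[ok]]) / sum(w[ok])
  }, numeric(1))
  edges <- c(1:5, (n - 4):n, n + 1:5, (2 * n - 4):(2 * n))
  expect_equal(cc$A[edges], oracle[edges], tolerance = 1e-12)
  # interior equals input
  interior <- setdiff(seq_along(x), edges)
  expect_identical(cc$A[interior], x[interior])
})

test_that("the full pipeline composes and preserves shape until concatenation", {
  g <- default_study_graphs()$resting
  sim <- simulate_panel(g, study_subjects(2), seed = 8)
  stage1 <- regress_confounds(sim$panel, sim$confounds)
  stage2 <- highpass(stage1)
  stage3 <- center_per_subject(stage2)
  expect_equal(dim(stage1), dim(sim$panel))
  expect_equal(dim(stage2), dim(sim$panel))
  expect_equal(dim(stage3), dim(sim$panel))
  cc <- preprocess(sim$panel, sim$confounds, "motor")
  expect_s3_class(cc, "bg_concat")
  expect_equal(nrow(cc), 2 * 2 * 100)
  expect_true(all(is.finite(as.matrix(tibble::as_tibble(cc)[roi_labels(cc)]))))
})
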