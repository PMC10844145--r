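#' Regress the shared nuisance signal out of every ROI
#'
#' Per block and ROI, replaces the series by the residual of an ordinary
#' least-squares fit on an intercept plus the block's confound series (the
#' white-matter/ventricle mean signal stand-in). Output shape equals input
#' shape.
#'
#' @param panel A `bg_panel` tibble.
#' @param confounds Tibble aligned one-to-one with the panel's blocks
#'   (`subject_id`, `condition`, `block_index`, `volume`, `confound`).
#' @return A `bg_panel` of residuals.
#' @export
regress_confounds <- function(panel, confounds) {
  rois <- roi_labels(panel)
  key_cols <- c("subject_id", "condition", "block_index")
  merged <- dplyr::left_join(panel, confounds,
                             by = c(key_cols, "volume"))
  if (anyNA(merged$confound)) {
    bad <- dplyr::distinct(merged[is.na(merged$confound), key_cols])
    stop("confounds misaligned with panel for block(s): ",
         paste(do.call(paste, c(bad, sep = "/")), collapse = ", "))
  }
  out <- merged %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) %>%
    dplyr::group_modify(function(d, key) {
      X <- cbind(1, d$confound)
      fit <- qr(X)
      d[rois] <- lapply(d[rois], function(y) as.numeric(qr.resid(fit, y)))
      d
    }) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"confound")
  as_bg_panel(out[names(panel)], rois, attr(panel, "tr"))
}

#' High-pass filter by discrete-cosine basis projection
#'
#' Removes, per block and ROI, the projection onto the discrete-cosine basis
#' functions whose frequencies lie strictly below `cutoff_hz` (including the
#' constant term), i.e. drift and slow physiological trends. Projection on
#' short blocks is edge-transient free, unlike an IIR filter, and exactly
#' reproducible.
#'
#' @param panel A `bg_panel`.
#' @param cutoff_hz Cutoff frequency in Hz (default 0.009).
#' @return Filtered `bg_panel`; each block/ROI has mean zero.
#' @export
highpass <- function(panel, cutoff_hz = 0.009) {
  if (cutoff_hz <= 0) stop("cutoff_hz must be > 0")
  rois <- roi_labels(panel)
  tr <- attr(panel, "tr")
  key_cols <- c("subject_id", "condition", "block_index")
  out <- panel %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) %>%
    dplyr::group_modify(function(d, key) {
      B <- dct_basis(nrow(d), tr, cutoff_hz)
      fit <- qr(B)
      d[rois] <- lapply(d[rois], function(y) as.numeric(qr.resid(fit, y)))
      d
    }) %>%
    dplyr::ungroup()
  as_bg_panel(out[names(panel)], rois, tr)
}

# DCT-II basis columns with frequency k / (2 n tr) < cutoff (k = 0 is the
# constant), plus an explicit linear-drift column: the low-order cosines
# approximate a ramp only to ~88% of its energy, and drift must go
# completely.
dct_basis <- function(n, tr, cutoff_hz) {
  kmax <- ceiling(2 * n * tr * cutoff_hz) - 1
  k <- 0:max(0, kmax)
  t <- seq_len(n) - 0.5
  B <- vapply(k, function(kk) cos(pi * kk * t / n), numeric(n))
  cbind(B, t - mean(t))
}

#' Centre each subject's series around its mean
#'
#' Subtracts, per (subject, condition, ROI), the mean over that subject's
#' same-condition samples (all of the subject's blocks of that condition
#' jointly). Variance is preserved; set `zscore = TRUE` to also divide by the
#' per-subject standard deviation.
#'
#' @param panel A `bg_panel`.
#' @param zscore Also scale to unit variance? Default `FALSE`.
#' @return Centred `bg_panel`.
#' @export
center_per_subject <- function(panel, zscore = FALSE) {
  rois <- roi_labels(panel)
  out <- panel %>%
    dplyr::group_by(.data$subject_id, .data$condition) %>%
    dplyr::mutate(dplyr::across(dplyr::all_of(rois), function(y) {
      y <- y - mean(y)
      if (zscore) y <- y / sd(y)
      y
    })) %>%
    dplyr::ungroup()
  as_bg_panel(out, rois, attr(panel, "tr"))
}

#' Concatenate same-condition blocks with Gaussian boundary smoothing
#'
#' Joins all blocks of one condition in lexicographic (subject, block index)
#' order into a single multivariate series, then replaces only the first and
#' last 5 samples of each block by a centred Gaussian-weighted moving average
#' of window size 5 (sigma = 1 sample) computed within the concatenated
#' series, so windows at a join mix adjacent blocks and smooth the
#' transition. Interior samples are untouched.
#'
#' @param panel A `bg_panel`.
#' @param condition Which condition to concatenate.
#' @param smooth_halfwidth Number of samples at each block edge to smooth
#'   (default 5, the window size).
#' @return A `bg_concat` tibble with column `t` and one column per ROI;
#'   attributes `condition`, `boundaries` (1-based block start indices),
#'   `roi_labels`, `tr`, `block_order`.
#' @export
concatenate_blocks <- function(panel, condition, smooth_halfwidth = 5L) {
  rois <- roi_labels(panel)
  sel <- panel[panel$condition == condition, , drop = FALSE]
  if (nrow(sel) == 0) stop("no blocks of condition '", condition, "'")
  sel <- dplyr::arrange(sel, .data$subject_id, .data$block_index,
                        .data$volume)
  order_tbl <- dplyr::distinct(sel, .data$subject_id, .data$block_index)
  lens <- sel %>%
    dplyr::count(.data$subject_id, .data$block_index) %>%
    dplyr::arrange(.data$subject_id, .data$block_index)
  boundaries <- cumsum(c(1L, utils::head(lens$n, -1)))
  X <- as.matrix(sel[rois])
  X <- smooth_block_edges(X, boundaries, lens$n, smooth_halfwidth)
  out <- tibble::as_tibble(X)
  out <- dplyr::bind_cols(tibble::tibble(t = seq_len(nrow(out))), out)
  structure(out, condition = condition, boundaries = boundaries,
            roi_labels = rois, tr = attr(panel, "tr"),
            block_order = order_tbl,
            class = c("bg_concat", class(out)))
}

# Gaussian moving average (window 5, sigma 1) applied to the first and last
# `hw` samples of each block, windows evaluated on the full concatenated
# series (truncated and renormalized at the series ends).
smooth_block_edges <- function(X, starts, lens, hw = 5L) {
  if (hw <= 0) return(X)
  n <- nrow(X)
  w <- exp(-((-2):2)^2 / 2)
  targets <- unlist(purrr::map2(starts, lens, function(s, L) {
    c(s:min(s + hw - 1, s + L - 1), max(s, s + L - hw):(s + L - 1))
  }))
  targets <- sort(unique(targets))
  sm <- X
  for (t in targets) {
    idx <- (t - 2):(t + 2)
    ok <- idx >= 1 & idx <= n
    ww <- w[ok] / sum(w[ok])
    sm[t, ] <- ww %*% X[idx[ok], , drop = FALSE]
  }
  sm
}

#' Full preprocessing pipeline for one condition
#'
#' Runs the conditioning stages in order: nuisance regression, discrete-cosine
#' high-pass, per-subject mean-centring, and same-condition concatenation
#' with boundary smoothing.
#'
#' @inheritParams regress_confounds
#' @inheritParams highpass
#' @inheritParams concatenate_blocks
#' @param zscore Scale each subject's series to unit variance (default
#'   `FALSE`: centring only).
#' @return A `bg_concat` series.
#' @examples
#' g <- default_study_graphs()$resting
#' sim <- simulate_panel(g, study_subjects(2), seed = 1)
#' cc <- preprocess(sim$panel, sim$confounds, condition = "resting")
#' nrow(cc)  # 2 subjects x 2 blocks x 100 volumes = 400
#' @export
preprocess <- function(panel, confounds, condition, cutoff_hz = 0.009,
                       smooth_halfwidth = 5L, zscore = FALSE) {
  panel %>%
    regress_confounds(confounds) %>%
    highpass(cutoff_hz) %>%
    center_per_subject(zscore = zscore) %>%
    concatenate_blocks(condition, smooth_halfwidth)
}

#' @export
print.bg_concat <- function(x, ...) {
  cat(sprintf("<concatenated panel: condition '%s', %d samples x %d ROIs, %d blocks>\n",
              attr(x, "condition"), nrow(x), length(roi_labels(x)),
              length(attr(x, "boundaries"))))
  NextMethod()
}
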