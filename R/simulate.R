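#' Subject specification for the synthetic-data generator
#'
#' Describes one scanned subject: how many blocks were recorded per
#' experimental condition, the block length in volumes, and the repetition
#' time. Defaults mirror the study design this package emulates: two blocks
#' of 100 volumes per condition at a repetition time of 1.6 s, under a
#' resting and a motor condition.
#'
#' @param subject_id Character id.
#' @param blocks_per_condition Number of blocks per condition (default 2).
#' @param block_length Volumes per block (default 100, minimum 20).
#' @param tr Repetition time in seconds (default 1.6).
#' @param conditions Condition labels (default `c("resting", "motor")`).
#' @param condition_graph_overrides Optional named list mapping a condition
#'   label to a [ground_truth_graph()] used for that condition instead of the
#'   panel-level graph.
#' @return A `bg_subject_spec` list.
#' @export
subject_spec <- function(subject_id, blocks_per_condition = 2L,
                         block_length = 100L, tr = 1.6,
                         conditions = c("resting", "motor"),
                         condition_graph_overrides = NULL) {
  stopifnot(is.character(subject_id), length(subject_id) == 1)
  block_length <- as.integer(block_length)
  if (block_length < 20L) stop("block_length must be >= 20")
  if (tr <= 0) stop("tr must be > 0")
  if (anyDuplicated(conditions)) stop("condition labels must be unique")
  if (!is.null(condition_graph_overrides)) {
    if (!all(names(condition_graph_overrides) %in% conditions)) {
      stop("condition_graph_overrides must be named by condition")
    }
  }
  structure(list(subject_id = subject_id,
                 blocks_per_condition = as.integer(blocks_per_condition),
                 block_length = block_length, tr = tr,
                 conditions = conditions,
                 condition_graph_overrides = condition_graph_overrides),
            class = "bg_subject_spec")
}

#' A study-shaped roster of subjects
#'
#' Convenience wrapper building `n` identical [subject_spec()]s named
#' `sub01, sub02, ...`; the study's concatenation arithmetic uses 20.
#'
#' @param n Number of subjects.
#' @param ... Passed to [subject_spec()].
#' @return List of `bg_subject_spec`.
#' @export
study_subjects <- function(n = 20L, ...) {
  lapply(seq_len(n), function(i) {
    subject_spec(sprintf("sub%02d", i), ...)
  })
}

as_bg_panel <- function(tbl, roi_labels, tr) {
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "roi_labels") <- roi_labels
  attr(tbl, "tr") <- tr
  class(tbl) <- c("bg_panel", class(tbl))
  tbl
}

#' ROI labels of a panel
#' @param x A `bg_panel` or `bg_concat` object.
#' @return Character vector of ROI column names.
#' @export
roi_labels <- function(x) {
  attr(x, "roi_labels") %||%
    if (is.matrix(x)) colnames(x) else
      setdiff(names(x),
              c("subject_id", "condition", "block_index", "volume", "t"))
}

#' Simulate a multi-subject ROI panel from a ground-truth graph
#'
#' Generates each block independently per (subject, condition, block) with a
#' burn-in of 50 discarded steps. Linear links add
#' `coefficient * x_source(t - lag)` to the target's mean, quadratic links add
#' `coefficient * x_source(t - lag)^2`, and multiplicative-noise links scale
#' the target's innovation standard deviation by
#' `1 + |coefficient * x_source(t - lag)|`. Each node carries an AR(1) term
#' (its `autocorr`) standing in for hemodynamic smoothness. A shared
#' low-frequency confound (three sinusoids below 0.009 Hz plus a linear
#' drift) is added to every ROI with per-ROI loadings drawn uniformly from
#' \[0.5, 1.5\], and returned separately so the preprocessing stage has a
#' nuisance regressor to remove.
#'
#' Per-block seeds are derived from `seed` by a counter scheme, so extending
#' the subject roster never changes earlier subjects' data, and identical
#' inputs give bit-identical output.
#'
#' @param graph A [ground_truth_graph()].
#' @param subjects List of [subject_spec()] (or a single spec).
#' @param seed Integer master seed (required; no implicit entropy).
#' @param confound Logical; set `FALSE` to skip the shared nuisance component.
#' @return A list with `panel` (a `bg_panel` tibble: `subject_id`,
#'   `condition`, `block_index`, `volume`, one column per ROI) and
#'   `confounds` (tibble with the same keys plus `confound`).
#' @examples
#' g <- ground_truth_graph(c("A", "B"),
#'   data.frame(from = "A", to = "B", lag = 1, form = "linear",
#'              coefficient = 0.8))
#' sim <- simulate_panel(g, study_subjects(2), seed = 1)
#' dplyr::count(sim$panel, condition)
#' @export
simulate_panel <- function(graph, subjects, seed, confound = TRUE) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  stopifnot(inherits(graph, "bg_graph_truth"))
  if (inherits(subjects, "bg_subject_spec")) subjects <- list(subjects)
  blocks <- list()
  confs <- list()
  counter <- 0L
  for (sub in subjects) {
    stopifnot(inherits(sub, "bg_subject_spec"))
    for (cond in sub$conditions) {
      g <- sub$condition_graph_overrides[[cond]] %||% graph
      if (!identical(g$nodes, graph$nodes)) {
        stop("condition override must share the panel's ROI labels")
      }
      for (b in seq_len(sub$blocks_per_condition)) {
        counter <- counter + 1L
        bl <- simulate_block(g, sub$block_length, sub$tr,
                             derive_seed(seed, counter), confound)
        key <- tibble::tibble(subject_id = sub$subject_id, condition = cond,
                              block_index = b,
                              volume = seq_len(sub$block_length))
        blocks[[counter]] <- dplyr::bind_cols(key, tibble::as_tibble(bl$x))
        confs[[counter]] <- dplyr::bind_cols(key,
                                             tibble::tibble(confound = bl$confound))
      }
    }
  }
  tr <- subjects[[1]]$tr
  list(panel = as_bg_panel(dplyr::bind_rows(blocks), graph$nodes, tr),
       confounds = dplyr::bind_rows(confs))
}

# One block: burn-in, structural generation in lag-0 topological order,
# shared confound added with per-ROI loadings.
simulate_block <- function(graph, block_length, tr, block_seed,
                           confound = TRUE, burn_in = 50L) {
  set.seed(block_seed)
  nodes <- graph$nodes
  n <- length(nodes)
  total <- burn_in + block_length
  tau <- max(1L, graph$tau_max)
  ord <- attr(graph, "lag0_order") %||% lag0_order(graph)
  lk <- graph$links
  x <- matrix(0, total, n, dimnames = list(NULL, nodes))
  eps <- matrix(rnorm(total * n), total, n, dimnames = list(NULL, nodes))
  by_target <- split(seq_len(nrow(lk)), lk$to)
  for (t in seq_len(total)) {
    for (node in ord) {
      mu <- if (t > 1) graph$autocorr[[node]] * x[t - 1, node] else 0
      scale <- 1
      for (r in by_target[[node]]) {
        l <- lk[r, ]
        if (l$lag >= t) next
        src <- x[t - l$lag, l$from]
        if (l$form == "linear") mu <- mu + l$coefficient * src
        else if (l$form == "quadratic") mu <- mu + l$coefficient * src^2
        else scale <- scale * (1 + abs(l$coefficient * src))
      }
      x[t, node] <- mu + graph$noise_sd[[node]] * scale * eps[t, node]
    }
  }
  x <- x[(burn_in + 1):total, , drop = FALSE]
  if (confound) {
    cf <- make_confound(block_length, tr)
    loadings <- runif(n, 0.5, 1.5)
    x <- x + outer(cf, loadings)
  } else {
    cf <- rep(0, block_length)
  }
  list(x = x, confound = cf)
}

# Shared nuisance signal: three sinusoids with frequencies drawn below the
# 0.009 Hz high-pass cutoff plus a linear drift, mimicking respiration /
# scanner-drift aggregates as recorded in white matter and ventricles.
make_confound <- function(block_length, tr) {
  t_sec <- (seq_len(block_length) - 1) * tr
  freqs <- runif(3, 0.001, 0.009)
  phases <- runif(3, 0, 2 * pi)
  amps <- runif(3, 0.5, 1)
  cf <- rowSums(vapply(1:3, function(k) {
    amps[k] * sin(2 * pi * freqs[k] * t_sec + phases[k])
  }, numeric(block_length)))
  drift <- runif(1, 0.5, 1.5) * (t_sec - mean(t_sec)) / max(t_sec)
  cf + drift
}

#' Default study-shaped ground-truth graphs
#'
#' Two 9-node graphs over the basal-ganglia motor-circuit labels
#' (M1, S1, Cau, Put, GPe, STN, GPi, SN, Tal), one per condition. Both
#' contain at least one link of each functional form and each lag in
#' \{0, 1, 2\}, plus one reciprocal lag-2 pair (the "interactive"
#' relationship between thalamus and caudate). The resting and motor graphs
#' differ: the thalamo-putaminal lag-1 drive is present at rest and replaced
#' by a cortico-putaminal drive under the motor condition, which also gains a
#' pallido-nigral contemporaneous link.
#'
#' @param seed Integer; stored with the graphs for provenance (the topology
#'   and coefficients are fixed).
#' @return Named list with elements `resting` and `motor`, each a
#'   `bg_graph_truth`.
#' @export
default_study_graphs <- function(seed = 1L) {
  nodes <- c("M1", "S1", "Cau", "Put", "GPe", "STN", "GPi", "SN", "Tal")
  # quadratic (and multiplicative) sources are kept zero-mean by design:
  # a quadratic target inherits a positive mean from E[x^2], and squaring a
  # non-zero-mean source would add a genuine linear component (the 2*mu*x
  # cross-term), defeating the correlation-invisibility of the form
  common <- tibble::tribble(
    ~from, ~to,   ~lag, ~form,                  ~coefficient,
    "Tal", "Cau", 2L,   "linear",               0.4,
    "Cau", "Tal", 2L,   "linear",               0.4,
    "M1",  "S1",  0L,   "linear",               0.5,
    "Put", "GPe", 1L,   "linear",               0.5,
    "GPe", "STN", 1L,   "linear",               0.4,
    "S1",  "GPi", 2L,   "quadratic",            0.4,
    "SN",  "Tal", 2L,   "quadratic",            0.3,
    "Tal", "M1",  0L,   "multiplicative_noise", 0.8
  )
  resting <- dplyr::bind_rows(common, tibble::tibble(
    from = "Tal", to = "Put", lag = 1L, form = "linear", coefficient = 0.5))
  motor <- dplyr::bind_rows(common, tibble::tibble(
    from = "S1", to = "Put", lag = 1L, form = "linear", coefficient = 0.5))
  out <- list(
    resting = ground_truth_graph(nodes, resting, noise_sd = 1, autocorr = 0.4),
    motor = ground_truth_graph(nodes, motor, noise_sd = 1, autocorr = 0.4)
  )
  attr(out, "seed") <- seed
  out
}

#' Linear-only 9-node benchmark graph
#'
#' The linear skeleton used by the graph-recovery harness: the resting study
#' graph with its non-linear and heteroscedastic links replaced by linear
#' ones, so partial-correlation discovery has a fully linear target.
#'
#' @return A `bg_graph_truth`.
#' @export
linear_study_graph <- function() {
  g <- default_study_graphs()$resting
  links <- g$links
  links$coefficient[links$form != "linear"] <- 0.4
  links$form <- "linear"
  ground_truth_graph(g$nodes, links, noise_sd = 1, autocorr = 0.4)
}

#' Write / read a panel as delimited text plus a JSON sidecar
#'
#' One tab-separated file per block (header row of ROI labels, one row per
#' volume) and a `panel.json` sidecar listing blocks with subject, condition,
#' block index, file name and repetition time. Confounds use the same layout
#' with a single column.
#'
#' @param sim List with `panel` and `confounds` as from [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  panel <- sim$panel
  rois <- roi_labels(panel)
  keys <- dplyr::distinct(panel, .data$subject_id, .data$condition,
                          .data$block_index)
  entries <- purrr::pmap(keys, function(subject_id, condition, block_index) {
    blk <- panel[panel$subject_id == subject_id &
                   panel$condition == condition &
                   panel$block_index == block_index, rois]
    file <- sprintf("%s_%s_%02d.tsv", subject_id, condition, block_index)
    readr::write_tsv(blk, file.path(dir, file), progress = FALSE)
    cfile <- NA_character_
    if (!is.null(sim$confounds)) {
      cf <- sim$confounds[sim$confounds$subject_id == subject_id &
                            sim$confounds$condition == condition &
                            sim$confounds$block_index == block_index,
                          "confound"]
      cfile <- sprintf("%s_%s_%02d_confound.tsv", subject_id, condition,
                       block_index)
      readr::write_tsv(cf, file.path(dir, cfile), progress = FALSE)
    }
    list(subject_id = subject_id, condition = condition,
         block_index = block_index, file = file, confound_file = cfile,
         tr = attr(panel, "tr"))
  })
  jsonlite::write_json(list(roi_labels = rois, tr = attr(panel, "tr"),
                            blocks = entries),
                       file.path(dir, "panel.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "panel.json"))
  rois <- unlist(meta$roi_labels)
  blocks <- purrr::map(meta$blocks, function(e) {
    blk <- readr::read_tsv(file.path(dir, e$file), show_col_types = FALSE,
                           progress = FALSE)
    key <- tibble::tibble(subject_id = e$subject_id, condition = e$condition,
                          block_index = as.integer(e$block_index),
                          volume = seq_len(nrow(blk)))
    cf <- if (!is.null(e$confound_file) && !is.na(e$confound_file)) {
      readr::read_tsv(file.path(dir, e$confound_file),
                      show_col_types = FALSE, progress = FALSE)$confound
    } else rep(NA_real_, nrow(blk))
    list(panel = dplyr::bind_cols(key, blk),
         conf = dplyr::bind_cols(key, tibble::tibble(confound = cf)))
  })
  list(panel = as_bg_panel(dplyr::bind_rows(purrr::map(blocks, "panel")),
                           rois, meta$tr),
       confounds = dplyr::bind_rows(purrr::map(blocks, "conf")))
}
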