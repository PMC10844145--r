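#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected
#' (pass a list via `do.call(pipeline_config, cfg)` to validate one read
#' from a file).
#'
#' @param out_dir Run directory to create.
#' @param input_dir Directory holding a panel written by [write_panel()];
#'   `NULL` simulates instead.
#' @param n_subjects,blocks_per_condition,block_length,tr Simulation shape
#'   used when `input_dir` is `NULL` (defaults: the study's 20 subjects, 2
#'   blocks per condition, 100 volumes at 1.6 s).
#' @param conditions Condition labels (tasks).
#' @param seeds Seed ROIs analysed against the remaining nuclei; each
#'   discovery run subsets the panel to one seed plus its partners.
#' @param methods CI regimes to run (default all three).
#' @param cutoff_hz,smooth_halfwidth,zscore,mask_boundaries Preprocessing
#'   options.
#' @param tau_max,alpha,n_permutations,max_samples Discovery options.
#' @param scheme Statistic normalisation scheme for the relationship table.
#' @param master_seed Master seed; every stage derives from it.
#' @return A validated `bg_pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            input_dir = NULL,
                            n_subjects = 20L,
                            blocks_per_condition = 2L,
                            block_length = 100L,
                            tr = 1.6,
                            conditions = c("resting", "motor"),
                            seeds = "Tal",
                            methods = c("parcorr", "gpdc", "cmiknn"),
                            cutoff_hz = 0.009,
                            smooth_halfwidth = 5L,
                            zscore = FALSE,
                            mask_boundaries = FALSE,
                            tau_max = 2L,
                            alpha = 0.01,
                            n_permutations = 500L,
                            max_samples = 500L,
                            scheme = "max_abs",
                            master_seed = 1L) {
  stopifnot(is.character(out_dir), length(out_dir) == 1,
            alpha > 0, alpha < 1, tau_max >= 1, n_permutations >= 99,
            cutoff_hz > 0, length(conditions) >= 1,
            all(methods %in% c("parcorr", "gpdc", "cmiknn")))
  structure(as.list(environment()), class = "bg_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulation (or panel ingestion), preprocessing per condition, PCMCI+
#' discovery per (method, task, seed subset) — mirroring the study design in
#' which each thalamic seed is analysed separately against the other nuclei
#' — and relationship classification. Writes into the run directory:
#' `concat_<condition>.tsv` with JSON metadata, one `graph_*.json` and
#' `links_*.csv` per discovery run, `table.csv`, `summary.json`, and
#' `provenance.json`. All numeric outputs are reproducible from the inputs
#' and the master seed alone; timestamps live only in the provenance file.
#'
#' @param cfg A [pipeline_config()].
#' @return The run directory path, invisibly; the relationship table is
#'   written to `table.csv` and returned in the attribute `"table"`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "bg_pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- stage("input", {
    if (is.null(cfg$input_dir)) {
      graphs <- default_study_graphs(cfg$master_seed)
      overrides <- graphs[intersect(names(graphs), cfg$conditions)]
      subs <- study_subjects(cfg$n_subjects,
                             blocks_per_condition = cfg$blocks_per_condition,
                             block_length = cfg$block_length, tr = cfg$tr,
                             conditions = cfg$conditions,
                             condition_graph_overrides = overrides)
      simulate_panel(graphs[[1]], subs, seed = derive_seed(cfg$master_seed, 1L))
    } else {
      read_panel(cfg$input_dir)
    }
  })

  concat <- stage("preprocess", {
    out <- lapply(cfg$conditions, function(cond) {
      cc <- preprocess(sim$panel, sim$confounds, cond,
                       cutoff_hz = cfg$cutoff_hz,
                       smooth_halfwidth = cfg$smooth_halfwidth,
                       zscore = cfg$zscore)
      readr::write_tsv(tibble::as_tibble(cc)[roi_labels(cc)],
                       file.path(cfg$out_dir,
                                 sprintf("concat_%s.tsv", cond)),
                       progress = FALSE)
      jsonlite::write_json(
        list(condition = cond, n = nrow(cc),
             boundaries = attr(cc, "boundaries"),
             order = attr(cc, "block_order"),
             options = list(cutoff_hz = cfg$cutoff_hz,
                            smooth_halfwidth = cfg$smooth_halfwidth,
                            zscore = cfg$zscore)),
        file.path(cfg$out_dir, sprintf("concat_%s.json", cond)),
        auto_unbox = TRUE, digits = NA)
      cc
    })
    stats::setNames(out, cfg$conditions)
  })

  runs <- tidyr::expand_grid(method = cfg$methods, task = cfg$conditions,
                             seed = cfg$seeds)
  graphs <- stage("discover", {
    purrr::pmap(runs, function(method, task, seed) {
      idx <- 100L + which(runs$method == method & runs$task == task &
                            runs$seed == seed)[1]
      cc <- concat[[task]]
      keep <- union(seed, setdiff(roi_labels(cc), cfg$seeds))
      sub <- subset_concat(cc, keep)
      dcfg <- discovery_config(
        tau_max = cfg$tau_max, alpha = cfg$alpha, ci_method = method,
        seed = derive_seed(cfg$master_seed, idx),
        n_permutations = cfg$n_permutations,
        max_samples = cfg$max_samples,
        mask_boundaries = cfg$mask_boundaries)
      g <- discover(sub, dcfg)
      tag <- sprintf("%s_%s_%s", canon_method(method), task, seed)
      write_graph_json(g, file.path(cfg$out_dir,
                                    sprintf("graph_%s.json", tag)))
      readr::write_csv(tidy(g),
                       file.path(cfg$out_dir, sprintf("links_%s.csv", tag)),
                       progress = FALSE)
      g
    })
  })

  table <- stage("classify", {
    rel <- build_relationship_table(
      dplyr::mutate(runs, graph = graphs), scheme = cfg$scheme)
    readr::write_csv(tidy(rel), file.path(cfg$out_dir, "table.csv"),
                     progress = FALSE)
    jsonlite::write_json(as.list(glance(rel)),
                         file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    rel
  })

  jsonlite::write_json(
    list(config = unclass(cfg)[setdiff(names(cfg), "")],
         package_version = as.character(utils::packageVersion("bgcausal")),
         r_version = R.version.string,
         started = format(t0), finished = format(Sys.time()),
         wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    file.path(cfg$out_dir, "provenance.json"), auto_unbox = TRUE,
    digits = NA, null = "null")
  structure(invisible(cfg$out_dir), table = table)
}

subset_concat <- function(cc, keep) {
  out <- tibble::as_tibble(cc)[c("t", keep)]
  structure(out, condition = attr(cc, "condition"),
            boundaries = attr(cc, "boundaries"), roi_labels = keep,
            tr = attr(cc, "tr"), block_order = attr(cc, "block_order"),
            class = c("bg_concat", class(out)))
}

write_graph_json <- function(graph, path) {
  links <- tidy(graph, all = TRUE)
  cfg <- attr(graph, "config")
  jsonlite::write_json(
    list(nodes = attr(graph, "nodes"),
         links = links,
         config = cfg[c("tau_max", "alpha", "ci_method", "pc_alpha",
                        "seed", "n_permutations", "max_samples")]),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
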