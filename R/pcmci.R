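#' Configuration for PCMCI+ causal discovery
#'
#' @param tau_max Maximum lag `T` in sampling steps (default 2; at the study's
#'   1.6 s repetition time this spans 3.2 s).
#' @param alpha Two-sided significance level for link detection (default
#'   0.01).
#' @param ci_method Conditional-independence regime: `"parcorr"`, `"gpdc"`,
#'   or `"cmiknn"`.
#' @param pc_alpha Level for the condition-selection phase (defaults to
#'   `alpha`).
#' @param max_conds Cap on conditioning-set size per side (default `Inf`;
#'   the 9-node, lag-2 search space needs no cap).
#' @param seed Integer master seed; every CI test derives its own seed from
#'   it by a counter, so results are reproducible and order-stable.
#' @param n_permutations Permutations per CI test (default 500).
#' @param block_length Permutation block length (`NULL` = automatic rule).
#' @param max_samples Subsampling cap for `gpdc`/`cmiknn` (default 500).
#' @param k `cmiknn` neighbour count (`NULL` = `max(5, 0.1 n)`).
#' @param mask_boundaries Exclude lag windows crossing block boundaries.
#' @return A `bg_discovery_config` list.
#' @export
discovery_config <- function(tau_max = 2L, alpha = 0.01,
                             ci_method = c("parcorr", "gpdc", "cmiknn"),
                             pc_alpha = alpha, max_conds = Inf, seed = 1L,
                             n_permutations = 500L, block_length = NULL,
                             max_samples = 500L, k = NULL,
                             mask_boundaries = FALSE) {
  ci_method <- match.arg(ci_method)
  stopifnot(alpha > 0, alpha < 1, tau_max >= 1)
  structure(list(tau_max = as.integer(tau_max), alpha = alpha,
                 ci_method = ci_method, pc_alpha = pc_alpha,
                 max_conds = max_conds, seed = as.integer(seed),
                 n_permutations = as.integer(n_permutations),
                 block_length = block_length, max_samples = max_samples,
                 k = k, mask_boundaries = mask_boundaries),
            class = "bg_discovery_config")
}

# A CI test bound to the discovery configuration; `counter` makes per-test
# seeds deterministic and independent of evaluation order elsewhere.
run_ci <- function(data, i, j, lag, conds, cfg, counter) {
  ci_test(data, i, j, lag, conds, method = cfg$ci_method, alpha = cfg$alpha,
          n_permutations = cfg$n_permutations,
          block_length = cfg$block_length,
          seed = derive_seed(cfg$seed, counter),
          k = cfg$k, max_samples = cfg$max_samples, tau_max = cfg$tau_max,
          mask_boundaries = cfg$mask_boundaries)
}

new_counter <- function() {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  function() {
    env$n <- env$n + 1L
    env$n
  }
}

# Deterministic candidate ordering: descending |statistic|, ties broken by
# (node index, lag).
order_candidates <- function(cand, nodes) {
  cand[order(-abs(cand$stat), match(cand$node, nodes), cand$lag), ,
       drop = FALSE]
}

#' PC-style condition selection (first PCMCI+ stage)
#'
#' For every target node, iteratively prunes the candidate parents: at
#' iteration `q` each surviving candidate is tested conditional on the `q`
#' strongest other surviving candidates (by absolute statistic), and removed
#' when its p-value exceeds `pc_alpha`. Lagged (lag 1..T) and contemporaneous
#' (lag 0) candidate pools are processed separately; the contemporaneous pass
#' additionally conditions on the already-selected lagged parents of the
#' target. Separating sets of removed pairs are recorded for the collider
#' phase.
#'
#' @param data A `bg_concat` series.
#' @param cfg A [discovery_config()].
#' @return A `bg_parent_sets`: named list (one element per target) of
#'   tibbles `(node, lag, stat)` ordered by selection strength, with
#'   attribute `sepsets`.
#' @export
select_conditions <- function(data, cfg) {
  nodes <- roi_labels(data)
  n_total <- nrow(data)
  if (n_total <= 10 * length(nodes) * (cfg$tau_max + 1)) {
    stop("series too short for reliable selection: need n > 10 N (T+1)")
  }
  tick <- new_counter()
  sepsets <- list()
  note_sepset <- function(i, lag, j, conds) {
    sepsets[[paste(i, lag, j, sep = "|")]] <<- conds
  }

  prune_pool <- function(target, cand, extra_conds) {
    # q = 0: unconditional (plus any fixed extra conditions)
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      res <- run_ci(data, cand$node[r], target, cand$lag[r], extra_conds,
                    cfg, tick())
      cand$stat[r] <- res$statistic
      keep[r] <- res$p_value <= cfg$pc_alpha
      if (!keep[r]) note_sepset(cand$node[r], cand$lag[r], target,
                                extra_conds)
    }
    cand <- cand[keep, , drop = FALSE]
    q <- 1L
    while (q <= nrow(cand) - 1L) {
      cand <- order_candidates(cand, nodes)
      keep <- logical(nrow(cand))
      for (r in seq_len(nrow(cand))) {
        others <- cand[-r, , drop = FALSE]
        Z <- utils::head(others[, c("node", "lag")], q)
        Z <- dplyr::bind_rows(Z, extra_conds)
        Z <- utils::head(dplyr::distinct(Z), min(cfg$max_conds, nrow(Z)))
        res <- run_ci(data, cand$node[r], target, cand$lag[r], Z, cfg,
                      tick())
        cand$stat[r] <- res$statistic
        keep[r] <- res$p_value <= cfg$pc_alpha
        if (!keep[r]) note_sepset(cand$node[r], cand$lag[r], target, Z)
      }
      cand <- cand[keep, , drop = FALSE]
      q <- q + 1L
    }
    order_candidates(cand, nodes)
  }

  empty_conds <- tibble::tibble(node = character(), lag = integer())
  parents <- stats::setNames(vector("list", length(nodes)), nodes)
  for (target in nodes) {
    lagged <- tidyr::expand_grid(node = nodes, lag = seq_len(cfg$tau_max))
    lagged$stat <- NA_real_
    lagged <- prune_pool(target, lagged, empty_conds)
    contemp <- tibble::tibble(node = setdiff(nodes, target), lag = 0L,
                              stat = NA_real_)
    contemp <- prune_pool(target, contemp,
                          lagged[, c("node", "lag")])
    parents[[target]] <- order_candidates(dplyr::bind_rows(lagged, contemp),
                                          nodes)
  }
  structure(parents, sepsets = sepsets, nodes = nodes,
            class = "bg_parent_sets")
}

parents_of <- function(parents, node, drop = NULL, cap = Inf,
                       pool = c("all", "lagged", "contemp")) {
  pool <- match.arg(pool)
  p <- parents[[node]][, c("node", "lag")]
  if (pool == "lagged") p <- p[p$lag > 0, , drop = FALSE]
  if (pool == "contemp") p <- p[p$lag == 0, , drop = FALSE]
  if (!is.null(drop)) {
    p <- p[!(p$node == drop[[1]] & p$lag == as.integer(drop[[2]])), ,
           drop = FALSE]
  }
  utils::head(p, min(cap, nrow(p)))
}

#' Momentary conditional independence tests (second PCMCI+ stage)
#'
#' For each ordered pair and lag, tests the link conditional on the selected
#' parents of the target (minus the tested source) together with the
#' lag-shifted parents of the source — the MCI construction that makes the
#' statistic robust to autocorrelation and common drivers. When the pair has
#' selected contemporaneous neighbours the test is run twice — once with
#' lagged conditions only and once adding the contemporaneous neighbours —
#' and the larger p-value is kept: the first conditioning leaks through
#' contemporaneous mediators, the second can open autocorrelation colliders
#' through an undirected neighbour that is really the target's child, and a
#' genuine link survives both. Lagged links with `p <= alpha` are oriented
#' past-to-present; significant lag-0 links enter as undirected pending
#' orientation.
#'
#' @param data A `bg_concat` series.
#' @param parents A `bg_parent_sets` from [select_conditions()] on the same
#'   data.
#' @param cfg The same [discovery_config()].
#' @return A `bg_tsgraph`: tibble of link records (`i`, `j`, `lag`, `mark`,
#'   `statistic`, `p_value`, `conds`) carrying all tested pairs (mark
#'   `"absent"` when not significant), with attributes `nodes`, `config`,
#'   `sepsets`.
#' @export
mci_tests <- function(data, parents, cfg) {
  nodes <- attr(parents, "nodes")
  tick <- new_counter()
  # seeds for MCI tests must not collide with the selection phase
  base <- 1000000L

  clean <- function(Z, i, j, lag) {
    Z <- dplyr::distinct(Z)
    Z[!(Z$node == j & Z$lag == 0L) & !(Z$node == i & Z$lag == lag), ,
      drop = FALSE]
  }
  # run under both conditioning sets and keep the worse p (see docs)
  dual_test <- function(i, j, lag, Z_lag, Z_full) {
    res <- run_ci(data, i, j, lag, Z_lag, cfg, base + tick())
    Z_used <- Z_lag
    if (nrow(Z_full) > nrow(Z_lag)) {
      res2 <- run_ci(data, i, j, lag, Z_full, cfg, base + tick())
      if (res2$p_value > res$p_value) {
        res <- res2
        Z_used <- Z_full
      }
    } else {
      tick()  # keep the seed stream aligned whether or not a 2nd test runs
    }
    list(res = res, Z = Z_used)
  }

  rows <- list()
  for (j in nodes) {
    for (lag in seq_len(cfg$tau_max)) {
      for (i in nodes) {
        Zj <- parents_of(parents, j, drop = list(i, lag),
                         cap = cfg$max_conds, pool = "lagged")
        Zi <- parents_of(parents, i, cap = cfg$max_conds, pool = "lagged")
        Zi$lag <- Zi$lag + lag
        Z_lag <- clean(dplyr::bind_rows(Zj, Zi), i, j, lag)
        Zc <- parents_of(parents, j, drop = list(i, lag),
                         cap = cfg$max_conds, pool = "contemp")
        Z_full <- clean(dplyr::bind_rows(Z_lag, Zc), i, j, lag)
        ans <- dual_test(i, j, lag, Z_lag, Z_full)
        rows[[length(rows) + 1]] <- tibble::tibble(
          i = i, j = j, lag = lag,
          mark = if (ans$res$p_value <= cfg$alpha) "directed" else "absent",
          statistic = ans$res$statistic, p_value = ans$res$p_value,
          conds = list(ans$Z))
      }
    }
  }
  for (a in seq_along(nodes)) {
    for (b in seq_along(nodes)) {
      if (a >= b) next
      i <- nodes[a]; j <- nodes[b]
      Zj_l <- parents_of(parents, j, cap = cfg$max_conds, pool = "lagged")
      Zi_l <- parents_of(parents, i, cap = cfg$max_conds, pool = "lagged")
      Z_lag <- clean(dplyr::bind_rows(Zj_l, Zi_l), i, j, 0L)
      Zj_c <- parents_of(parents, j, drop = list(i, 0L),
                         cap = cfg$max_conds, pool = "contemp")
      Zi_c <- parents_of(parents, i, drop = list(j, 0L),
                         cap = cfg$max_conds, pool = "contemp")
      Z_full <- clean(dplyr::bind_rows(Zj_c, Zi_c, Z_lag), i, j, 0L)
      ans <- dual_test(i, j, 0L, Z_lag, Z_full)
      rows[[length(rows) + 1]] <- tibble::tibble(
        i = i, j = j, lag = 0L,
        mark = if (ans$res$p_value <= cfg$alpha) "contemp_undirected" else
          "absent",
        statistic = ans$res$statistic, p_value = ans$res$p_value,
        conds = list(ans$Z))
    }
  }
  links <- dplyr::bind_rows(rows)
  structure(links, nodes = nodes, config = cfg,
            sepsets = attr(parents, "sepsets"),
            class = c("bg_tsgraph", class(links)))
}

#' Orient contemporaneous links (collider and rule phases)
#'
#' Collider phase: for every unshielded triple — a lagged directed link or a
#' contemporaneous link into a middle node `k` that is also contemporaneously
#' tied to `j`, with the outer pair non-adjacent — the `k`-`j` tie is
#' oriented into `k` when `k` is not needed to separate the outer pair.
#' Whether `k` separates is decided by explicit conditional-independence
#' tests on the data (outer pair tested given the lagged conditions with and
#' without `k` at lag 0): the lagged selection phase can never place a lag-0
#' node in its separating sets, so stored sepsets alone would over-fire the
#' collider rule. If the outer pair is independent without `k`, the triple is
#' a collider and the tie is oriented into `k`; if it becomes independent
#' only when `k` is added, `k` is a mediator and a lagged triple orients the
#' tie out of `k`. Rule phase: Meek-style propagation (orient to avoid new
#' unshielded colliders and 2-cycles). Contradictory demands on a link yield
#' `contemp_conflict`, never a silent overwrite; unresolved links stay
#' `contemp_undirected`.
#'
#' @param graph A `bg_tsgraph` from [mci_tests()].
#' @param data The `bg_concat` series the graph was discovered on (required
#'   for the orientation tests; with `NULL`, only the rule phase runs).
#' @param parents The `bg_parent_sets` used for the MCI tests.
#' @param cfg The [discovery_config()].
#' @return The graph with contemporaneous marks oriented where possible;
#'   directed lag-0 records use mark `"contemp_directed"` with `i` the cause.
#' @export
orient_contemporaneous <- function(graph, data = NULL, parents = NULL,
                                   cfg = NULL) {
  links <- tibble::as_tibble(graph)
  und <- which(links$mark == "contemp_undirected")
  if (length(und) == 0) return(graph)

  sig <- links[links$mark != "absent", , drop = FALSE]
  adj0 <- function(a, b) {
    any(sig$lag == 0 & ((sig$i == a & sig$j == b) | (sig$i == b & sig$j == a)))
  }

  # orientation state per undirected lag-0 record: "none", "i->j", "j->i",
  # "conflict"
  state <- rep("none", nrow(links))
  demand <- function(r, dir) {
    cur <- state[r]
    if (cur == "none") state[r] <<- dir
    else if (cur != dir) state[r] <<- "conflict"
  }

  # --- collider phase (data-driven separation checks) ---
  if (!is.null(data) && !is.null(parents) && !is.null(cfg)) {
    tick <- new_counter()
    base <- 2000000L
    cache <- new.env(parent = emptyenv())
    indep <- function(i, tau, jj, with_k = NULL) {
      key <- paste(i, tau, jj, paste(with_k, collapse = ","), sep = "|")
      if (!is.null(cache[[key]])) return(cache[[key]])
      Zj <- parents_of(parents, jj, drop = list(i, tau),
                       cap = cfg$max_conds, pool = "lagged")
      Zi <- parents_of(parents, i, cap = cfg$max_conds, pool = "lagged")
      Zi$lag <- Zi$lag + tau
      Z <- dplyr::distinct(dplyr::bind_rows(Zj, Zi))
      if (!is.null(with_k)) {
        Z <- dplyr::bind_rows(tibble::tibble(node = with_k, lag = 0L), Z)
      }
      Z <- Z[!(Z$node == jj & Z$lag == 0L) &
               !(Z$node == i & Z$lag == tau), , drop = FALSE]
      res <- run_ci(data, i, jj, tau, dplyr::distinct(Z), cfg,
                    base + tick())
      cache[[key]] <- res$p_value > cfg$alpha
      cache[[key]]
    }

    for (r in und) {
      k <- links$i[r]; j <- links$j[r]
      for (swap in c(FALSE, TRUE)) {
        kk <- if (swap) j else k
        jj <- if (swap) k else j
        to_kk <- if (swap) "i->j" else "j->i"   # arrow into the middle node
        to_jj <- if (swap) "j->i" else "i->j"
        # lagged triples: i -> kk at tau > 0, outer pair (i, tau, jj) absent
        lag_in <- sig[sig$mark == "directed" & sig$j == kk, , drop = FALSE]
        for (q in seq_len(nrow(lag_in))) {
          i <- lag_in$i[q]; tau <- lag_in$lag[q]
          if (i == jj) next
          if (any(sig$lag == tau & sig$i == i & sig$j == jj &
                    sig$mark == "directed")) next
          if (indep(i, tau, jj)) {
            demand(r, to_kk)          # collider: jj -> kk
          } else if (indep(i, tau, jj, with_k = kk)) {
            demand(r, to_jj)          # mediator: kk -> jj
          }
        }
        # contemporaneous triples i o-o kk o-o jj, (i, jj) non-adjacent
        con_in <- sig[sig$lag == 0 & (sig$i == kk | sig$j == kk), ,
                      drop = FALSE]
        for (q in seq_len(nrow(con_in))) {
          i <- if (con_in$i[q] == kk) con_in$j[q] else con_in$i[q]
          if (i == jj || adj0(i, jj)) next
          if (indep(i, 0L, jj)) demand(r, to_kk)
          # a contemporaneous mediator gives no direction information
        }
      }
    }
  }

  apply_state <- function() {
    for (r in und) {
      if (state[r] == "conflict") {
        links$mark[r] <<- "contemp_conflict"
      } else if (state[r] == "j->i") {
        links[r, c("i", "j")] <<- links[r, c("j", "i")]
        links$mark[r] <<- "contemp_directed"
        state[r] <<- "i->j"
      } else if (state[r] == "i->j") {
        links$mark[r] <<- "contemp_directed"
      }
    }
  }
  apply_state()

  # --- rule phase (Meek R1/R2 on the contemporaneous skeleton) ---
  repeat {
    changed <- FALSE
    dir0 <- links[links$mark == "contemp_directed", , drop = FALSE]
    for (r in which(links$mark == "contemp_undirected")) {
      a <- links$i[r]; b <- links$j[r]
      for (swap in c(FALSE, TRUE)) {
        x <- if (swap) b else a
        y <- if (swap) a else b
        # R1: i -> x, x o-o y, i and y non-adjacent  =>  x -> y
        into_x <- dir0$i[dir0$j == x]
        if (any(vapply(into_x, function(i) i != y && !adj0(i, y),
                       logical(1)))) {
          demand(r, if (swap) "j->i" else "i->j")
          changed <- TRUE
        }
        # R2: x -> w -> y and x o-o y  =>  x -> y
        w_out <- dir0$j[dir0$i == x]
        if (any(vapply(w_out, function(w) any(dir0$i == w & dir0$j == y),
                       logical(1)))) {
          demand(r, if (swap) "j->i" else "i->j")
          changed <- TRUE
        }
      }
    }
    apply_state()
    if (!changed) break
  }

  structure(links, nodes = attr(graph, "nodes"),
            config = attr(graph, "config"),
            sepsets = attr(graph, "sepsets"),
            class = c("bg_tsgraph", class(links)))
}

#' PCMCI+ causal discovery
#'
#' Runs the full pipeline: condition selection, momentary conditional
#' independence tests, and contemporaneous orientation. All randomness is
#' derived from `cfg$seed`; identical data and seed give identical graphs.
#'
#' @param data A `bg_concat` series (from [preprocess()] or
#'   [concatenate_blocks()]), or a plain numeric matrix.
#' @param cfg A [discovery_config()].
#' @return A `bg_tsgraph` with full provenance attached (`config`, per-link
#'   conditioning sets).
#' @examples
#' \donttest{
#' g <- ground_truth_graph(c("A", "B", "C"),
#'   data.frame(from = c("A", "B"), to = c("B", "C"), lag = 1,
#'              form = "linear", coefficient = 0.7), autocorr = 0.3)
#' sim <- simulate_panel(g, study_subjects(4, conditions = "resting"),
#'                       seed = 2, confound = FALSE)
#' cc <- concatenate_blocks(sim$panel, "resting")
#' discover(cc, discovery_config(tau_max = 2, seed = 2,
#'                               n_permutations = 199))
#' }
#' @export
discover <- function(data, cfg = discovery_config()) {
  parents <- select_conditions(data, cfg)
  graph <- mci_tests(data, parents, cfg)
  graph <- orient_contemporaneous(graph, data, parents, cfg)
  attr(graph, "parents") <- parents
  graph
}

#' @export
print.bg_tsgraph <- function(x, ...) {
  sig <- x[x$mark != "absent", , drop = FALSE]
  cat(sprintf("<time-series graph: %d nodes, %d significant links (of %d tested)>\n",
              length(attr(x, "nodes")), nrow(sig), nrow(x)))
  if (nrow(sig)) {
    print(tibble::as_tibble(sig[, c("i", "j", "lag", "mark", "statistic",
                                    "p_value")]), n = Inf)
  }
  invisible(x)
}

#' Tidy a discovered time-series graph
#'
#' @param x A `bg_tsgraph`.
#' @param all Include non-significant (absent) records? Default `FALSE`.
#' @param ... Unused.
#' @return A tibble of link records.
#' @export
tidy.bg_tsgraph <- function(x, all = FALSE, ...) {
  out <- tibble::as_tibble(x)
  if (!all) out <- out[out$mark != "absent", , drop = FALSE]
  out$conds <- purrr::map_chr(out$conds, function(z) {
    if (is.null(z) || nrow(z) == 0) "" else
      paste(sprintf("%s(-%d)", z$node, z$lag), collapse = ";")
  })
  out
}

#' One-row summary of a discovered graph
#'
#' @param x A `bg_tsgraph`.
#' @param ... Unused.
#' @return A one-row tibble: node count, tested and significant link counts
#'   by mark, configuration echo.
#' @export
glance.bg_tsgraph <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    n_nodes = length(attr(x, "nodes")),
    n_tested = nrow(x),
    n_links = sum(x$mark != "absent"),
    n_directed = sum(x$mark == "directed"),
    n_contemp_directed = sum(x$mark == "contemp_directed"),
    n_contemp_undirected = sum(x$mark == "contemp_undirected"),
    n_conflict = sum(x$mark == "contemp_conflict"),
    ci_method = cfg$ci_method %||% NA_character_,
    alpha = cfg$alpha %||% NA_real_,
    tau_max = cfg$tau_max %||% NA_integer_
  )
}
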