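# Small generative fixtures shared across the suite. Everything is built in
# code at test time; no stored data.

chain_graph <- function(coef = 0.7, autocorr = 0.3) {
  ground_truth_graph(
    c("A", "B", "C"),
    data.frame(from = c("A", "B"), to = c("B", "C"), lag = 1,
               form = "linear", coefficient = coef),
    autocorr = autocorr)
}

common_driver_graph <- function(autocorr = 0.3) {
  ground_truth_graph(
    c("A", "B", "D"),
    data.frame(from = "D", to = c("A", "B"), lag = 1, form = "linear",
               coefficient = 0.6),
    autocorr = autocorr)
}

# one long single-subject block, no confound
single_series <- function(graph, n, seed) {
  sim <- simulate_panel(
    graph,
    subject_spec("s1", blocks_per_condition = 1L, block_length = n,
                 conditions = "resting"),
    seed = seed, confound = FALSE)
  concatenate_blocks(sim$panel, "resting", smooth_halfwidth = 0L)
}

# AR(1) pair with independent margins (the autocorrelated null)
ar1_pair <- function(n, phi = 0.8, seed = 1) {
  set.seed(seed)
  x <- as.numeric(stats::arima.sim(list(ar = phi), n))
  y <- as.numeric(stats::arima.sim(list(ar = phi), n))
  cbind(X = x, Y = y)
}

# matrix of ROI columns of a panel
concat_panel_matrix <- function(panel) as.matrix(panel[roi_labels(panel)])

# naive O(n^2) double-sum distance correlation (independent oracle)
dcor_naive <- function(x, y) {
  n <- length(x)
  A <- as.matrix(stats::dist(x, method = "manhattan"))
  B <- as.matrix(stats::dist(y, method = "manhattan"))
  Ac <- A - outer(rowMeans(A), rep(1, n)) - outer(rep(1, n), colMeans(A)) +
    mean(A)
  Bc <- B - outer(rowMeans(B), rep(1, n)) - outer(rep(1, n), colMeans(B)) +
    mean(B)
  dcov2 <- mean(Ac * Bc)
  sqrt(dcov2 / sqrt(mean(Ac * Ac) * mean(Bc * Bc)))
}

# map a collapsed relationship table back to method-level link records
uncollapse_relationships <- function(rel) {
  purrr::pmap_dfr(tidy(rel), function(seed, partner, task, lag, lag_class,
                                      role, nature, methods_detecting,
                                      statistic_normalized, sign, ...) {
    methods <- strsplit(methods_detecting, "\\+")[[1]]
    dirs <- switch(role, undefined = "u", causative = "c", response = "r",
                   interactive = c("c", "r"))
    tidyr::expand_grid(method = methods, direction = dirs) |>
      dplyr::mutate(seed = seed, partner = partner, task = task, lag = lag,
                    value = statistic_normalized)
  })
}

# ---- brute-force d-separation oracle on the unrolled generative graph ----
# Nodes are (name, time offset <= 0). The graph is unrolled far enough back
# that every tested path is represented. Classic reachability ("Bayes ball")
# over the unrolled DAG; all link forms count as edges, and autocorr > 0
# adds a self-edge at lag 1.
unrolled_edges <- function(graph, depth) {
  links <- graph$links[, c("from", "to", "lag")]
  auto <- names(graph$autocorr)[graph$autocorr > 0]
  links <- rbind(links, data.frame(from = auto, to = auto, lag = 1L))
  out <- list()
  for (t in 0:-depth) {
    for (r in seq_len(nrow(links))) {
      src_t <- t - links$lag[r]
      if (src_t < -depth) next
      out[[length(out) + 1]] <- data.frame(
        from = paste0(links$from[r], "@", src_t),
        to = paste0(links$to[r], "@", t))
    }
  }
  do.call(rbind, out)
}

d_separated <- function(graph, i, lag_i, j, conds, depth = 6) {
  edges <- unrolled_edges(graph, depth)
  x <- paste0(i, "@", -lag_i)
  y <- paste0(j, "@", 0)
  z <- if (length(conds) && nrow(conds)) {
    paste0(conds$node, "@", -conds$lag)
  } else character(0)
  if (x == y) return(FALSE)
  pa <- split(edges$from, edges$to)
  ch <- split(edges$to, edges$from)
  anc_of_z <- character(0)
  frontier <- z
  while (length(frontier)) {
    anc_of_z <- union(anc_of_z, frontier)
    frontier <- setdiff(unlist(pa[frontier], use.names = FALSE), anc_of_z)
  }
  # states: (node, direction) with direction "up" (entered from a child)
  # or "down" (entered from a parent)
  seen <- character(0)
  queue <- list(c(x, "up"))
  while (length(queue)) {
    st <- queue[[1]]; queue <- queue[-1]
    key <- paste(st, collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    node <- st[1]; dir <- st[2]
    if (node == y && node != x) return(FALSE)
    in_z <- node %in% z
    if (dir == "up" && !in_z) {
      for (p in pa[[node]] %||% character(0)) queue <- c(queue, list(c(p, "up")))
      for (cc in ch[[node]] %||% character(0)) queue <- c(queue, list(c(cc, "down")))
    } else if (dir == "down") {
      if (!in_z) {
        for (cc in ch[[node]] %||% character(0)) {
          queue <- c(queue, list(c(cc, "down")))
        }
      }
      if (node %in% anc_of_z) {
        for (p in pa[[node]] %||% character(0)) queue <- c(queue, list(c(p, "up")))
      }
    }
  }
  TRUE
}

`%||%` <- function(a, b) if (is.null(a)) b else a
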