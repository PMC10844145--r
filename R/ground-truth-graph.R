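#' Ground-truth time-series causal graph
#'
#' Constructs and validates the generative graph used by [simulate_panel()].
#' Nodes are ROI labels; links are lag-annotated directed effects whose
#' functional form is one of `"linear"` (adds `coefficient * x_source(t - lag)`
#' to the target), `"quadratic"` (adds `coefficient * x_source(t - lag)^2`),
#' or `"multiplicative_noise"` (scales the target's innovation standard
#' deviation by `1 + |coefficient * x_source(t - lag)|`).
#'
#' Construction fails unless the process implied by the linear part is
#' stationary: the spectral radius of the companion matrix of the reduced-form
#' vector autoregression (after solving out contemporaneous linear links,
#' whose lag-0 subgraph must be acyclic) must be strictly below 1. Each node
#' additionally carries a first-order autoregressive coefficient (`autocorr`,
#' the hemodynamic-smoothness stand-in) that enters the companion matrix.
#'
#' @param nodes Character vector of ROI labels.
#' @param links Data frame with columns `from`, `to`, `lag` (non-negative
#'   integer), `form` (one of `"linear"`, `"quadratic"`,
#'   `"multiplicative_noise"`), `coefficient`. May have zero rows.
#' @param noise_sd Innovation standard deviations; scalar or named per node.
#' @param autocorr Per-node AR(1) coefficients in `[0, 1)`; scalar or named.
#' @param tau_max Maximum lag the graph may use (default 2).
#'
#' @return An object of class `bg_graph_truth`: a list with elements `nodes`,
#'   `links` (tibble), `noise_sd`, `autocorr`, `tau_max`.
#' @examples
#' g <- ground_truth_graph(
#'   nodes = c("A", "B"),
#'   links = data.frame(from = "A", to = "B", lag = 1,
#'                      form = "linear", coefficient = 0.8)
#' )
#' g
#' @export
ground_truth_graph <- function(nodes, links = NULL, noise_sd = 1,
                               autocorr = 0, tau_max = 2L) {
  stopifnot(is.character(nodes), length(nodes) >= 1, !anyDuplicated(nodes))
  if (is.null(links) || nrow(links) == 0) {
    links <- tibble::tibble(from = character(), to = character(),
                            lag = integer(), form = character(),
                            coefficient = double())
  }
  links <- tibble::as_tibble(links)
  needed <- c("from", "to", "lag", "form", "coefficient")
  if (!all(needed %in% names(links))) {
    stop("`links` needs columns ", paste(needed, collapse = ", "))
  }
  links$lag <- as.integer(links$lag)
  forms <- c("linear", "quadratic", "multiplicative_noise")
  if (nrow(links) > 0) {
    if (!all(links$from %in% nodes) || !all(links$to %in% nodes)) {
      stop("link endpoints must be graph nodes")
    }
    if (!all(links$form %in% forms)) {
      stop("link `form` must be one of ", paste(forms, collapse = ", "))
    }
    if (any(links$lag < 0)) stop("lags must be non-negative")
    if (any(links$lag > tau_max)) stop("link lag exceeds tau_max = ", tau_max)
    if (any(links$lag == 0 & links$from == links$to)) {
      stop("self-links at lag 0 are not allowed")
    }
  }
  expand <- function(x, what) {
    if (length(x) == 1 && is.null(names(x))) {
      x <- stats::setNames(rep(as.double(x), length(nodes)), nodes)
    }
    if (!all(nodes %in% names(x))) stop(what, " must name every node")
    x[nodes]
  }
  noise_sd <- expand(noise_sd, "noise_sd")
  autocorr <- expand(autocorr, "autocorr")
  if (any(noise_sd <= 0)) stop("noise_sd must be > 0")
  if (any(autocorr < 0 | autocorr >= 1)) stop("autocorr must lie in [0, 1)")

  g <- structure(
    list(nodes = nodes, links = links, noise_sd = noise_sd,
         autocorr = autocorr, tau_max = as.integer(tau_max)),
    class = "bg_graph_truth"
  )
  ord <- lag0_order(g)  # errors on a cyclic lag-0 subgraph
  sr <- companion_spectral_radius(g)
  if (sr >= 1) {
    stop(sprintf(
      "graph is non-stationary: companion spectral radius %.3f >= 1", sr))
  }
  attr(g, "lag0_order") <- ord
  attr(g, "spectral_radius") <- sr
  g
}

#' @export
print.bg_graph_truth <- function(x, ...) {
  cat(sprintf("<ground-truth causal graph: %d nodes, %d links, rho = %.3f>\n",
              length(x$nodes), nrow(x$links), attr(x, "spectral_radius")))
  print(x$links, n = Inf)
  invisible(x)
}

# Topological order of the lag-0 subgraph (all forms count as edges).
lag0_order <- function(graph) {
  nodes <- graph$nodes
  e0 <- graph$links[graph$links$lag == 0, , drop = FALSE]
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (t in e0$to) indeg[t] <- indeg[t] + 1L
  ord <- character(0)
  ready <- names(indeg)[indeg == 0L]
  while (length(ready) > 0) {
    v <- ready[1]
    ready <- ready[-1]
    ord <- c(ord, v)
    out <- e0$to[e0$from == v]
    for (w in out) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) ready <- c(ready, w)
    }
  }
  if (length(ord) < length(nodes)) stop("lag-0 subgraph is cyclic")
  ord
}

# Spectral radius of the companion matrix of the reduced-form VAR implied by
# the linear links plus the per-node AR(1) terms. Quadratic links contribute
# no linear term (E[x^2] shifts the mean only); multiplicative-noise links
# affect the innovation scale, not the mean dynamics.
companion_spectral_radius <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  p <- max(1L, graph$tau_max)
  lin <- graph$links[graph$links$form == "linear", , drop = FALSE]
  B0 <- matrix(0, n, n, dimnames = list(nodes, nodes))
  Bl <- replicate(p, matrix(0, n, n, dimnames = list(nodes, nodes)),
                  simplify = FALSE)
  for (i in seq_len(nrow(lin))) {
    l <- lin[i, ]
    if (l$lag == 0) B0[l$to, l$from] <- B0[l$to, l$from] + l$coefficient
    else Bl[[l$lag]][l$to, l$from] <- Bl[[l$lag]][l$to, l$from] + l$coefficient
  }
  diag(Bl[[1]]) <- diag(Bl[[1]]) + graph$autocorr
  inv <- solve(diag(n) - B0)
  A <- do.call(cbind, lapply(Bl, function(b) inv %*% b))
  comp <- rbind(A, cbind(diag(n * (p - 1)), matrix(0, n * (p - 1), n)))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# Reduced-form VAR matrices (used by tests as an analytic oracle and by the
# stationary-variance computation).
reduced_form_var <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  p <- max(1L, graph$tau_max)
  lin <- graph$links[graph$links$form == "linear", , drop = FALSE]
  B0 <- matrix(0, n, n, dimnames = list(nodes, nodes))
  Bl <- replicate(p, matrix(0, n, n, dimnames = list(nodes, nodes)),
                  simplify = FALSE)
  for (i in seq_len(nrow(lin))) {
    l <- lin[i, ]
    if (l$lag == 0) B0[l$to, l$from] <- B0[l$to, l$from] + l$coefficient
    else Bl[[l$lag]][l$to, l$from] <- Bl[[l$lag]][l$to, l$from] + l$coefficient
  }
  diag(Bl[[1]]) <- diag(Bl[[1]]) + graph$autocorr
  inv <- solve(diag(n) - B0)
  list(A = lapply(Bl, function(b) inv %*% b),
       Sigma = inv %*% diag(graph$noise_sd^2, n) %*% t(inv))
}

# Stationary covariance of the linear-only process via the companion-form
# discrete Lyapunov equation, solved by vectorization.
stationary_covariance <- function(graph) {
  rf <- reduced_form_var(graph)
  n <- length(graph$nodes)
  p <- length(rf$A)
  A <- do.call(cbind, rf$A)
  comp <- rbind(A, cbind(diag(n * (p - 1)), matrix(0, n * (p - 1), n)))
  Q <- matrix(0, n * p, n * p)
  Q[seq_len(n), seq_len(n)] <- rf$Sigma
  vecS <- solve(diag((n * p)^2) - kronecker(comp, comp), as.vector(Q))
  S <- matrix(vecS, n * p, n * p)
  S[seq_len(n), seq_len(n), drop = FALSE]
}
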