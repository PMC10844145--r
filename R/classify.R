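#' Lag class of a relationship
#'
#' Maps a lag in sampling steps to the reporting classes used for
#' thalamus-basal-ganglia relationships: 0 is contemporaneous (within one
#' 1.6 s repetition time), 1 single-delayed, 2 double-delayed.
#'
#' @param lag Integer vector with values in 0..2.
#' @return Character vector of lag classes.
#' @export
lag_class <- function(lag) {
  if (any(lag < 0 | lag > 2)) stop("lag must be in 0..2")
  c("contemporaneous", "single_delayed", "double_delayed")[lag + 1]
}

#' Causal role of a set of links between one pair
#'
#' Given the marked links that one (seed, partner, task, lag-class) group
#' received, returns the causal role of the seed: `"undefined"` for
#' undirected or conflicted contemporaneous ties, `"causative"` when the
#' seed drives the partner, `"response"` when the partner drives the seed,
#' and `"interactive"` when delayed links run in both directions.
#'
#' @param links_between_pair Data frame with a `direction` column using codes
#'   `"u"` (undirected/conflict), `"c"` (seed to partner), `"r"` (partner to
#'   seed), and a `lag` column.
#' @return A single role string.
#' @export
assign_role <- function(links_between_pair) {
  if (is.null(links_between_pair) || nrow(links_between_pair) == 0) {
    stop("empty link set")
  }
  d <- unique(links_between_pair$direction)
  delayed <- any(links_between_pair$lag > 0)
  if (all(c("c", "r") %in% d) && delayed) return("interactive")
  if ("c" %in% d) return("causative")
  if ("r" %in% d) return("response")
  "undefined"
}

#' Nature of a relationship from the methods that detected it
#'
#' The triangulation rule: partial correlation only has power against linear
#' dependence, so a PC detection labels the relationship linear; GPDC detects
#' linear and non-linear dependence, so a GPDC-without-PC detection labels it
#' non-linear; a CMIknn-only detection labels it complex.
#'
#' @param methods_detecting Character vector, subset of
#'   `c("PC", "GPDC", "CMIknn")`.
#' @return `"linear"`, `"non_linear"`, or `"complex"`.
#' @export
assign_nature <- function(methods_detecting) {
  if (length(methods_detecting) == 0) stop("empty method set")
  if ("PC" %in% methods_detecting) return("linear")
  if ("GPDC" %in% methods_detecting) return("non_linear")
  "complex"
}

#' Normalise link statistics for cross-method comparison
#'
#' Per method, rescales the absolute statistic into `[0, 1]`; the sign (for
#' signed statistics such as partial correlation) is kept in a separate
#' column. The default scheme divides by the per-method maximum absolute
#' statistic; `"rank"` uses the per-method rank fraction instead.
#'
#' @param records Tibble of method-level links with columns `method` and
#'   `value`.
#' @param scheme `"max_abs"` (default) or `"rank"`.
#' @return `records` with columns `value_normalized` and `sign` added; the
#'   scheme is recorded in attribute `"scheme"`.
#' @export
normalize_statistics <- function(records, scheme = c("max_abs", "rank")) {
  scheme <- match.arg(scheme)
  out <- records %>%
    dplyr::group_by(.data$method) %>%
    dplyr::mutate(
      sign = sign(.data$value),
      value_normalized = {
        v <- abs(.data$value)
        if (all(is.na(v))) {
          NA_real_
        } else if (scheme == "rank") {
          rank(v, na.last = "keep") / sum(!is.na(v))
        } else {
          mx <- max(v, na.rm = TRUE)
          if (mx == 0) {
            warning("all-zero statistics in method group; normalised to 0")
            v * 0
          } else v / mx
        }
      }
    ) %>%
    dplyr::ungroup()
  attr(out, "scheme") <- scheme
  out
}

#' Collapse per-method link lists into relationship records
#'
#' The reporting unit is one record per (seed, partner, task, lag-class,
#' direction). Method-level links are first grouped; a contemporaneous
#' undirected tie is absorbed into a directed contemporaneous record of the
#' same pair and task when one exists; delayed links running in both
#' directions at the same lag merge into a single `"interactive"` record.
#' Each record's nature follows [assign_nature()] applied to the methods that
#' detected it, and its normalised statistic is the maximum per-method
#' normalised value among its contributing links.
#'
#' @param links Tibble of method-level links: `seed`, `task`, `method`
#'   (`PC`/`GPDC`/`CMIknn`), `partner`, `lag` (0..2), `direction`
#'   (`"u"`, `"c"`, `"r"`), and optionally `value`.
#' @param scheme Normalisation scheme, see [normalize_statistics()].
#' @return A `bg_relationships` tibble: `seed`, `partner`, `task`,
#'   `lag`, `lag_class`, `role`, `nature`, `methods_detecting`,
#'   `statistic_normalized`, `sign`.
#' @export
collapse_links <- function(links, scheme = "max_abs") {
  stopifnot(all(c("seed", "task", "method", "partner", "lag",
                  "direction") %in% names(links)))
  if (!"value" %in% names(links)) links$value <- NA_real_
  links <- normalize_statistics(links, scheme)
  grouped <- links %>%
    dplyr::group_by(.data$seed, .data$task, .data$partner, .data$lag,
                    .data$direction) %>%
    dplyr::summarise(
      methods = list(sort(unique(.data$method))),
      statistic_normalized = if (all(is.na(.data$value_normalized)))
        NA_real_ else max(.data$value_normalized, na.rm = TRUE),
      sign = .data$sign[which.max(abs(.data$value_normalized))[1]] %||%
        NA_real_,
      .groups = "drop")
  # absorb lag-0 undirected marks into a directed contemporaneous record
  grouped <- grouped %>%
    dplyr::group_by(.data$seed, .data$task, .data$partner) %>%
    dplyr::filter(!(.data$lag == 0 & .data$direction == "u" &
                      any(.data$lag == 0 & .data$direction != "u"))) %>%
    dplyr::ungroup()
  # merge delayed bidirectional pairs into one interactive record
  out <- grouped %>%
    dplyr::group_by(.data$seed, .data$task, .data$partner, .data$lag) %>%
    dplyr::summarise(
      role = assign_role(data.frame(direction = .data$direction,
                                    lag = .data$lag)),
      methods_detecting = list(sort(unique(unlist(.data$methods)))),
      statistic_normalized = if (all(is.na(.data$statistic_normalized)))
        NA_real_ else max(.data$statistic_normalized, na.rm = TRUE),
      sign = .data$sign[1],
      .groups = "drop")
  out$lag_class <- lag_class(out$lag)
  out$nature <- purrr::map_chr(out$methods_detecting, assign_nature)
  out <- out[order(out$seed, out$task, out$partner, out$lag),
             c("seed", "partner", "task", "lag", "lag_class", "role",
               "nature", "methods_detecting", "statistic_normalized",
               "sign")]
  structure(out, scheme = scheme,
            class = c("bg_relationships", class(out)))
}

#' Build the relationship table from per-method discovery graphs
#'
#' Restricts each method's discovered graph to links incident to the seed
#' ROI, converts marks to seed-relative directions, and collapses across
#' methods into the reporting records of [collapse_links()].
#'
#' @param graphs A tibble (or data frame) with columns `method`
#'   (`"PC"`, `"GPDC"`, `"CMIknn"`, or the `ci_method` names), `task`, and a
#'   list-column `graph` of `bg_tsgraph` objects; optionally `seed` with the
#'   seed ROI per row.
#' @param seed Seed ROI label used for rows lacking one.
#' @param scheme Normalisation scheme.
#' @return A `bg_relationships` tibble.
#' @export
build_relationship_table <- function(graphs, seed = NULL,
                                     scheme = "max_abs") {
  graphs <- tibble::as_tibble(graphs)
  if (!"seed" %in% names(graphs)) graphs$seed <- seed %||%
      stop("`seed` ROI label required")
  labels <- purrr::map(graphs$graph, attr, "nodes")
  if (length(unique(purrr::map_chr(labels, paste, collapse = ","))) > 1) {
    stop("graphs disagree on node labels")
  }
  rows <- purrr::pmap(graphs, function(method, task, graph, seed, ...) {
    graph_link_records(graph, seed = seed, task = task,
                       method = canon_method(method))
  })
  links <- dplyr::bind_rows(rows)
  if (nrow(links) == 0) {
    return(structure(
      tibble::tibble(seed = character(), partner = character(),
                     task = character(), lag = integer(),
                     lag_class = character(), role = character(),
                     nature = character(), methods_detecting = list(),
                     statistic_normalized = double(), sign = double()),
      class = c("bg_relationships", "tbl_df", "tbl", "data.frame")))
  }
  collapse_links(links, scheme)
}

canon_method <- function(m) {
  switch(tolower(m),
         parcorr = "PC", pc = "PC",
         gpdc = "GPDC",
         cmiknn = "CMIknn",
         stop("unknown method: ", m))
}

# Significant links of one graph incident to the seed, as seed-relative
# method-level records.
graph_link_records <- function(graph, seed, task, method) {
  g <- tibble::as_tibble(graph)
  g <- g[g$mark != "absent" & g$i != g$j &
           (g$i == seed | g$j == seed), , drop = FALSE]
  if (nrow(g) == 0) {
    return(tibble::tibble(seed = character(), task = character(),
                          method = character(), partner = character(),
                          lag = integer(), direction = character(),
                          value = double()))
  }
  tibble::tibble(
    seed = seed, task = task, method = method,
    partner = ifelse(g$i == seed, g$j, g$i),
    lag = g$lag,
    direction = dplyr::case_when(
      g$mark %in% c("contemp_undirected", "contemp_conflict") ~ "u",
      g$i == seed ~ "c",
      TRUE ~ "r"),
    value = g$statistic)
}

#' Published per-method link lists of the study
#'
#' Loads the packaged machine-readable transcription of the per-method
#' significant links printed for the three thalamic seeds (M-Tal, IL-Tal,
#' MD-Tal) against the basal-ganglia motor-circuit nuclei, under the resting
#' and motor tasks. `table2_relationships()` collapses them with
#' [collapse_links()]; the collapsed table contains 57 relationships of
#' which 35 are non-linear or complex.
#'
#' @param path Optional path to an alternative fixture file.
#' @return `read_table2_links()`: tibble of method-level links;
#'   `table2_relationships()`: a `bg_relationships` tibble.
#' @export
read_table2_links <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table2_links.csv",
                                package = "bgcausal", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  comment = "#")
}

#' @rdname read_table2_links
#' @export
table2_relationships <- function(path = NULL) {
  collapse_links(read_table2_links(path))
}

#' @export
print.bg_relationships <- function(x, ...) {
  cat(sprintf("<relationship table: %d records (%d linear, %d non-linear, %d complex)>\n",
              nrow(x), sum(x$nature == "linear"),
              sum(x$nature == "non_linear"), sum(x$nature == "complex")))
  y <- tibble::as_tibble(x)
  y$methods_detecting <- purrr::map_chr(y$methods_detecting, paste,
                                        collapse = "+")
  print(y, n = 20)
  invisible(x)
}

#' @export
tidy.bg_relationships <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$methods_detecting <- purrr::map_chr(out$methods_detecting, paste,
                                          collapse = "+")
  out
}

#' @export
glance.bg_relationships <- function(x, ...) {
  tibble::tibble(
    n_relationships = nrow(x),
    n_linear = sum(x$nature == "linear"),
    n_non_linear = sum(x$nature == "non_linear"),
    n_complex = sum(x$nature == "complex"),
    non_linear_fraction = if (nrow(x)) mean(x$nature != "linear") else
      NA_real_
  )
}
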