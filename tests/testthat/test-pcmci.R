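quick_cfg <- function(seed, ...) {
  discovery_config(tau_max = 2, seed = seed, n_permutations = 199, ...)
}

test_that("a lagged chain is recovered without the transitive shortcut", {
  g <- chain_graph(coef = 0.7)
  cc <- single_series(g, 2000, seed = 1)
  pa <- select_conditions(cc, quick_cfg(1))
  pc <- pa$C[pa$C$node != "C", ]
  expect_true(any(pc$node == "B" & pc$lag == 1))
  tg <- discover(cc, quick_cfg(1))
  d <- tidy(tg)
  expect_true(any(d$i == "A" & d$j == "B" & d$lag == 1 &
                    d$mark == "directed"))
  expect_true(any(d$i == "B" & d$j == "C" & d$lag == 1 &
                    d$mark == "directed"))
  # no A -> C link at any lag once B is conditioned on (d-separation)
  expect_false(any(d$i == "A" & d$j == "C"))
  # parents never contain the target at lag 0; no future -> past links
  for (nd in names(pa)) expect_false(any(pa[[nd]]$node == nd &
                                           pa[[nd]]$lag == 0))
  expect_true(all(d$lag >= 0))
  expect_true(all(d$mark[d$lag > 0] == "directed"))
})

test_that("an observed common driver leaves no spurious pair link", {
  g <- common_driver_graph()
  cc <- single_series(g, 2000, seed = 2)
  d <- tidy(discover(cc, quick_cfg(2)))
  expect_true(any(d$i == "D" & d$j == "A" & d$lag == 1))
  expect_true(any(d$i == "D" & d$j == "B" & d$lag == 1))
  expect_false(any((d$i == "A" & d$j == "B") | (d$i == "B" & d$j == "A")))
})

test_that("with empty parent sets MCI reduces to the unconditional test", {
  set.seed(3)
  m <- cbind(A = rnorm(400), B = rnorm(400))
  cfg <- quick_cfg(3)
  pa <- structure(list(A = tibble::tibble(node = character(),
                                          lag = integer(),
                                          stat = double()),
                       B = tibble::tibble(node = character(),
                                          lag = integer(),
                                          stat = double())),
                  nodes = c("A", "B"), sepsets = list(),
                  class = "bg_parent_sets")
  tg <- mci_tests(m, pa, cfg)
  row <- tg[tg$i == "A" & tg$j == "B" & tg$lag == 1, ]
  ref <- ci_test(m, "A", "B", lag = 1, method = "parcorr",
                 seed = 1, n_permutations = 199, tau_max = 2)
  expect_equal(row$statistic, ref$statistic, tolerance = 1e-12)
  expect_equal(nrow(row$conds[[1]]), 0)
})

test_that("a contemporaneous link with a lagged parent is oriented through the mediator rule", {
  g <- ground_truth_graph(
    c("A", "B", "D"),
    data.frame(from = c("D", "D", "A"), to = c("A", "B", "B"),
               lag = c(1, 1, 0), form = "linear",
               coefficient = c(0.6, 0.6, 0.5)),
    autocorr = 0.3)
  cc <- single_series(g, 2000, seed = 4)
  d <- tidy(discover(cc, quick_cfg(4)))
  ab <- d[d$lag == 0 & ((d$i == "A" & d$j == "B") |
                          (d$i == "B" & d$j == "A")), ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$mark, "contemp_directed")
  expect_equal(c(ab$i, ab$j), c("A", "B"))
})

test_that("a contemporaneous collider is oriented into the middle node", {
  g <- ground_truth_graph(
    c("A", "B", "K"),
    data.frame(from = c("A", "B"), to = "K", lag = 0, form = "linear",
               coefficient = 0.6),
    autocorr = 0.3)
  cc <- single_series(g, 3000, seed = 5)
  d <- tidy(discover(cc, quick_cfg(5)))
  ak <- d[d$lag == 0 & d$i == "A" & d$j == "K", ]
  bk <- d[d$lag == 0 & d$i == "B" & d$j == "K", ]
  expect_equal(ak$mark, "contemp_directed")
  expect_equal(bk$mark, "contemp_directed")
  expect_false(any(d$lag == 0 & ((d$i == "A" & d$j == "B") |
                                   (d$i == "B" & d$j == "A"))))
})

test_that("a latent contemporaneous confounder yields a conflict mark, not a silent orientation", {
  # K <- H -> J with H unobserved; lagged drivers make both collider
  # demands fire, which must surface as contemp_conflict
  g <- ground_truth_graph(
    c("I1", "I2", "K", "J", "H"),
    data.frame(from = c("I1", "I2", "H", "H"),
               to = c("K", "J", "K", "J"),
               lag = c(1, 1, 0, 0), form = "linear",
               coefficient = c(0.6, 0.6, 0.6, 0.6)),
    autocorr = 0.3)
  sim <- simulate_panel(
    g, subject_spec("s1", blocks_per_condition = 1L, block_length = 3000L,
                    conditions = "resting"),
    seed = 6, confound = FALSE)
  panel <- sim$panel[setdiff(names(sim$panel), "H")]
  panel <- bgcausal:::as_bg_panel(panel, c("I1", "I2", "K", "J"), 1.6)
  cc <- concatenate_blocks(panel, "resting", smooth_halfwidth = 0L)
  d <- tidy(discover(cc, quick_cfg(6)))
  kj <- d[d$lag == 0 & ((d$i == "K" & d$j == "J") |
                          (d$i == "J" & d$j == "K")), ]
  expect_equal(nrow(kj), 1)
  expect_equal(kj$mark, "contemp_conflict")
})

test_that("a graph without lag-0 links passes orientation unchanged", {
  g <- chain_graph()
  cc <- single_series(g, 1500, seed = 7)
  cfg <- quick_cfg(7)
  pa <- select_conditions(cc, cfg)
  tg <- mci_tests(cc, pa, cfg)
  out <- orient_contemporaneous(tg, cc, pa, cfg)
  expect_identical(tibble::as_tibble(out), tibble::as_tibble(tg))
})

test_that("discovery is bit-deterministic under a fixed seed", {
  g <- chain_graph()
  cc <- single_series(g, 800, seed = 8)
  t1 <- discover(cc, quick_cfg(8))
  t2 <- discover(cc, quick_cfg(8))
  expect_identical(tibble::as_tibble(t1)[names(t1) != "conds"],
                   tibble::as_tibble(t2)[names(t2) != "conds"])
  expect_identical(t1$statistic, t2$statistic)
})

test_that("tidy and glance summarise a discovered graph", {
  g <- chain_graph()
  cc <- single_series(g, 800, seed = 9)
  tg <- discover(cc, quick_cfg(9))
  td <- tidy(tg)
  expect_true(all(c("i", "j", "lag", "mark", "statistic", "p_value",
                    "conds") %in% names(td)))
  expect_true(all(td$p_value <= 0.01))
  gl <- glance(tg)
  expect_equal(gl$n_links, nrow(td))
  expect_equal(gl$ci_method, "parcorr")
  expect_equal(gl$n_tested, nrow(tibble::as_tibble(tg)))
})

test_that("short series are rejected by the selection precondition", {
  m <- matrix(rnorm(9 * 100), 100, 9,
              dimnames = list(NULL, paste0("R", 1:9)))
  expect_error(select_conditions(m, quick_cfg(1)), "too short")
})

test_that("autocorrelation alone does not inflate discovered links", {
  count_links <- function(phi) {
    sum(vapply(1:3, function(s) {
      g <- ground_truth_graph(paste0("N", 1:5), autocorr = phi)
      cc <- single_series(g, 2000, seed = 40 + s)
      d <- tidy(discover(cc, quick_cfg(40 + s)))
      sum(!(d$i == d$j & d$lag == 1))  # self lag-1 links are real under phi > 0
    }, numeric(1)))
  }
  n0 <- count_links(0)
  n8 <- count_links(0.8)
  # ~ alpha x 110 tests x 3 seeds ~ 3 expected; allow binomial slack
  expect_lte(n0, 9)
  expect_lte(n8, 9)
})
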