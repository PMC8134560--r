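test_that("closed-form shells: cliques, paths, clique plus pendant", {
  # complete graph K4: everyone in shell 3
  k4 <- expand.grid(i = 1:4, j = 1:4)
  k4 <- k4[k4$i < k4$j, ]
  a4 <- kshell_decomposition(vnet_from_graph(4, k4))
  expect_equal(a4$shell, rep(3L, 4))
  expect_equal(a4$k_max, 3L)

  # path a-b-c collapses to shell 1
  path <- data.frame(i = c(1, 2), j = c(2, 3))
  expect_equal(kshell_decomposition(vnet_from_graph(3, path))$shell,
               rep(1L, 3))

  # K4 plus a pendant: pendant in shell 1, clique in shell 3
  k4p <- rbind(k4, data.frame(i = 1, j = 5))
  a <- kshell_decomposition(vnet_from_graph(5, k4p))
  expect_equal(a$shell, c(3L, 3L, 3L, 3L, 1L))
  expect_equal(oracle_kshell(5, k4p), c(3L, 3L, 3L, 3L, 1L))

  # isolated node gets shell 0
  iso <- kshell_decomposition(vnet_from_graph(4, data.frame(i = 1, j = 2)))
  expect_equal(iso$shell, c(1L, 1L, 0L, 0L))
})

test_that("decomposition matches the brute-force oracle and igraph", {
  set.seed(33)
  for (rep in 1:40) {
    n <- sample(5:40, 1)
    edges <- random_graph(n, runif(1, 0.05, 0.5))
    net <- vnet_from_graph(n, edges)
    got <- kshell_decomposition(net)$shell
    expect_identical(got, oracle_kshell(n, edges))
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(edges))
      g <- igraph::add_edges(g, rbind(edges$i, edges$j))
    expect_identical(got, as.integer(igraph::coreness(g)))
  }
})

test_that("cores are nested and edge addition never lowers a shell", {
  set.seed(34)
  for (rep in 1:10) {
    n <- 25
    edges <- random_graph(n, 0.15)
    sh <- kshell_decomposition(vnet_from_graph(n, edges))$shell
    for (k in 1:max(1, max(sh))) {
      core_k <- which(sh >= k)
      core_k1 <- which(sh >= k + 1)
      expect_true(all(core_k1 %in% core_k))
    }
    # add one absent edge
    all_pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    have <- paste(edges$i, edges$j)
    absent <- all_pairs[!paste(all_pairs[, 1], all_pairs[, 2]) %in% have, ,
                        drop = FALSE]
    if (nrow(absent)) {
      pick <- absent[sample(nrow(absent), 1), ]
      edges2 <- rbind(edges, data.frame(i = pick[1], j = pick[2]))
      sh2 <- kshell_decomposition(vnet_from_graph(n, edges2))$shell
      expect_true(all(sh2 >= sh))
    }
  }
})

test_that("shell normalization maps to (0, 1] with k_max guard", {
  k4p <- rbind(expand.grid(i = 1:4, j = 1:4), data.frame(i = 1, j = 5))
  k4p <- k4p[k4p$i < k4p$j, ]
  a <- kshell_decomposition(vnet_from_graph(5, k4p))
  ns <- normalize_shells(a)
  expect_equal(max(ns), 1)
  expect_equal(ns[5], 1 / 3)

  a2 <- kshell_decomposition(vnet_from_graph(2, data.frame(i = integer(),
                                                           j = integer())))
  expect_error(normalize_shells(a2, subject = "s01"), "k_max = 0.*s01")

  # top-shell nodes of different subjects land on a common 1.0
  tri <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3))
  a3 <- kshell_decomposition(vnet_from_graph(3, tri))
  expect_equal(max(normalize_shells(a3)), max(ns))
})

test_that("occupancy histograms bin, normalize and report missing pools", {
  k5 <- expand.grid(i = 1:5, j = 1:5)
  k5 <- k5[k5$i < k5$j, ]
  a <- kshell_decomposition(vnet_from_graph(5, k5, region = rep("M", 5)))
  h <- occupancy_histogram(list(a), group = "g", n_bins = 15)
  expect_equal(h$modules$M$mass[15], 1)
  expect_equal(sum(h$modules$M$mass[-15]), 0)

  # masses sum to 1 within 1e-12 on a mixed network
  mix <- rbind(k5, data.frame(i = 1, j = 6))
  am <- kshell_decomposition(vnet_from_graph(6, mix,
                                             region = c(rep("M", 5), "P")))
  hm <- occupancy_histogram(list(am), group = "g")
  expect_lt(abs(sum(hm$modules$M$mass) - 1), 1e-12)
  expect_lt(abs(sum(hm$modules$P$mass) - 1), 1e-12)

  # empty module pool: missing, not zeros
  h2 <- occupancy_histogram(list(a), group = "g", modules = c("M", "Q"))
  expect_null(h2$modules$Q)

  # conservation: per-bin counts sum to the pooled node count
  total <- sum(vapply(hm$modules, function(m) sum(m$counts), numeric(1)))
  expect_equal(total, 6)
})

test_that("bin edges are half-open with a closed top bin", {
  # normalized shells at exactly 14/15 and 1 must land in the last bin;
  # just below 14/15 in bin 14
  fake <- structure(list(shell = c(14L, 15L, 13L), k_max = 15L,
                         nodes = data.frame(region = rep("M", 3))),
                    class = "shell_assignment")
  h <- occupancy_histogram(list(fake), group = "g", n_bins = 15)
  expect_equal(h$modules$M$counts[15], 2L)
  expect_equal(h$modules$M$counts[14], 1L)
})

test_that("SSE between occupancy histograms is a symmetric squared distance", {
  mk <- function(mass, group) {
    structure(list(group = group, n_bins = 15,
                   breaks = seq(0, 1, length.out = 16),
                   modules = list(M = list(mass = mass,
                                           counts = round(mass * 100),
                                           n = 100, n_isolated = 0))),
              class = "occupancy_histogram")
  }
  m1 <- c(1, rep(0, 14))
  m2 <- c(0, 1, rep(0, 13))
  expect_equal(sse_between_groups(list(mk(m1, "a"), mk(m1, "b")))$sse, 0)
  expect_equal(sse_between_groups(list(mk(m1, "a"), mk(m2, "b")))$sse, 2)
  set.seed(40)
  r1 <- stats::runif(15); r1 <- r1 / sum(r1)
  r2 <- stats::runif(15); r2 <- r2 / sum(r2)
  s12 <- sse_between_groups(list(mk(r1, "a"), mk(r2, "b")))$sse
  s21 <- sse_between_groups(list(mk(r2, "b"), mk(r1, "a")))$sse
  expect_equal(s12, s21)
  expect_gte(s12, 0)
})
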