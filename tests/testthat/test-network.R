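amap_from_mask <- function(mask) list(active = mask)

test_that("fROI labeling splits by anatomy and drops excluded regions", {
  dims <- c(10, 6, 3)
  labels <- array(0L, dim = dims)
  labels[1:3, 1:2, 1] <- 1L
  labels[6:8, 1:2, 1] <- 2L
  labels[1:2, 5:6, 3] <- 3L
  lm <- label_map(labels, names = c("1" = "BA(L)", "2" = "WA(L)",
                                    "3" = "Visual"), excluded = 3L)
  mask <- labels > 0L
  nodes <- label_frois(amap_from_mask(mask), lm)
  expect_setequal(unique(nodes$region), c("BA(L)", "WA(L)"))
  expect_equal(sum(nodes$region == "BA(L)"), 6)
  expect_equal(attr(nodes, "n_excluded"), 4L)

  # a single connected component spanning two labels splits 6 / 4
  labels2 <- array(0L, dim = c(10, 1, 1))
  labels2[1:6, 1, 1] <- 1L
  labels2[7:10, 1, 1] <- 2L
  lm2 <- label_map(labels2, names = c("1" = "A", "2" = "B"))
  mask2 <- labels2 > 0L
  nodes2 <- label_frois(amap_from_mask(mask2), lm2)
  expect_equal(as.vector(table(nodes2$region)[c("A", "B")]), c(6L, 4L))
  expect_equal(length(unique(nodes2$froi)), 2)

  # background-labelled active voxels are kept but flagged
  mask3 <- labels2 > 0L
  mask3[1, 1, 1] <- TRUE
  labels3 <- labels2
  labels3[1, 1, 1] <- 0L
  lm3 <- label_map(labels3, names = c("1" = "A", "2" = "B"))
  expect_warning(nodes3 <- label_frois(amap_from_mask(mask3), lm3),
                 "unlabeled")
  expect_equal(sum(nodes3$unlabeled), 1L)

  expect_error(label_frois(amap_from_mask(array(TRUE, c(2, 2, 2))), lm),
               "different grids")
})

test_that("voxel correlations have the exact symmetry properties", {
  p <- task_paradigm(2, 20, 30, 2.5)
  nt <- n_frames(p)
  set.seed(3)
  base <- rnorm(nt)
  arr <- array(rnorm(4 * nt), dim = c(4, 1, 1, nt))
  arr[2, 1, 1, ] <- arr[1, 1, 1, ]      # duplicate
  arr[3, 1, 1, ] <- -arr[1, 1, 1, ]     # sign flip
  scan <- subject_scan(arr, 4, p)
  nodes <- data.frame(node = 1:4, index = 1:4, region = "R", froi = "R#1")
  C <- voxel_correlations(scan, nodes)
  expect_equal(C[1, 2], 1)
  expect_equal(C[1, 3], -1)
  expect_equal(C, t(C))
  expect_equal(diag(C), rep(1, 4))
  expect_true(all(C >= -1 & C <= 1))
})

test_that("null correlations stay below 0.32 at T = 160", {
  set.seed(8)
  nt <- 160
  arr <- array(rnorm(50 * nt), dim = c(50, 1, 1, nt))
  scan <- subject_scan(arr, 4, task_paradigm(8, 20, 30, 2.5))
  nodes <- data.frame(node = 1:50, index = 1:50, region = "R", froi = "R#1")
  C <- voxel_correlations(scan, nodes)
  off <- abs(C[upper.tri(C)])
  # P(|r| >= 0.32) ~ 3e-5 per pair; 1225 pairs -> expect none
  expect_lt(max(off), 0.32)
})

test_that("voxel network applies the absolute-value threshold rule", {
  nodes <- data.frame(node = 1:3, index = 1:3, region = "R", froi = "R#1")
  C <- matrix(c(1, -0.9, 0.3,
                -0.9, 1, 0.55,
                0.3, 0.55, 1), 3, 3)
  net <- build_voxel_network(C, nodes, theta = 0.8)
  expect_equal(nrow(net$edges), 1)          # the -0.9 edge is kept
  expect_equal(net$edges$C, -0.9)
  expect_equal(net$negative_fraction, 1)

  net5 <- build_voxel_network(C, nodes, theta = 0.5)
  adj <- matrix(FALSE, 3, 3)
  adj[cbind(net5$edges$i, net5$edges$j)] <- TRUE
  expect_equal(adj | t(adj), abs(C) >= 0.5 & row(C) != col(C))

  expect_equal(nrow(build_voxel_network(C, nodes, theta = 0.95)$edges), 0)
  expect_error(build_voxel_network(C, nodes, theta = 1.5), "theta")
  expect_error(build_voxel_network(C, nodes, theta = 0), "theta")
})

test_that("fROI weights follow the size-normalized cross-link count", {
  # complete bipartite 2 x 2: W = 4 / (2 + 2) = 1
  edges <- expand.grid(i = 1:2, j = 3:4)
  net <- vnet_from_graph(4, edges, region = c("A", "A", "B", "B"))
  fw <- froi_weights(net, by = "region")
  expect_equal(fw$edges$W, 1)
  expect_equal(fw$edges$n_cross, 4L)

  # 2 cross links over sizes 10 + 10 -> 0.1
  edges2 <- data.frame(i = c(1, 2), j = c(11, 12))
  net2 <- vnet_from_graph(20, edges2, region = rep(c("A", "B"), each = 10))
  expect_equal(froi_weights(net2, by = "region")$edges$W, 0.1)

  # large sparsely connected pair: 2 links over 100 + 100 -> 0.01
  edges3 <- data.frame(i = c(1, 50), j = c(101, 150))
  net3 <- vnet_from_graph(200, edges3, region = rep(c("A", "B"), each = 100))
  expect_equal(froi_weights(net3, by = "region")$edges$W, 0.01)

  # intra-fROI edges contribute nothing
  edges4 <- rbind(edges2, data.frame(i = c(3, 4), j = c(4, 5)))
  expect_equal(froi_weights(vnet_from_graph(20, edges4,
                                            region = rep(c("A", "B"),
                                                         each = 10)),
                            by = "region")$edges$W, 0.1)
})

test_that("fROI weights equal the brute-force double-loop oracle", {
  set.seed(14)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    regions <- sample(paste0("R", 1:sample(2:5, 1)), n, replace = TRUE)
    edges <- random_graph(n, runif(1, 0.05, 0.4))
    net <- vnet_from_graph(n, edges, region = regions)
    got <- froi_weights(net, by = "region")$edges
    want <- oracle_froi_weights(net)
    got <- got[order(got$region_i, got$region_j),
               c("region_i", "region_j", "n_cross", "W")]
    want <- want[order(want$region_i, want$region_j), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("weight bound is attained exactly at complete bipartite connectivity", {
  set.seed(15)
  for (rep in 1:10) {
    si <- sample(2:12, 1)
    sj <- sample(2:12, 1)
    edges <- expand.grid(i = seq_len(si), j = si + seq_len(sj))
    net <- vnet_from_graph(si + sj, edges,
                           region = rep(c("A", "B"), c(si, sj)))
    W <- froi_weights(net, by = "region")$edges$W
    expect_equal(W, si * sj / (si + sj))

    # removing one cross edge strictly decreases W below the bound
    net2 <- vnet_from_graph(si + sj, edges[-1, ],
                            region = rep(c("A", "B"), c(si, sj)))
    expect_lt(froi_weights(net2, by = "region")$edges$W, W)
  }
})

test_that("networks are invariant under node relabeling", {
  set.seed(16)
  n <- 30
  edges <- random_graph(n, 0.2)
  regions <- rep(c("A", "B", "C"), length.out = n)
  perm <- sample(n)
  net1 <- vnet_from_graph(n, edges, region = regions)
  edges2 <- data.frame(i = perm[edges$i], j = perm[edges$j])
  net2 <- vnet_from_graph(n, edges2, region = regions[order(perm)])
  f1 <- froi_weights(net1, by = "region")$edges
  f2 <- froi_weights(net2, by = "region")$edges
  f1 <- f1[order(f1$region_i, f1$region_j), ]
  f2 <- f2[order(f2$region_i, f2$region_j), ]
  rownames(f1) <- rownames(f2) <- NULL
  expect_equal(f1, f2)
  s1 <- sort(kshell_decomposition(net1)$shell)
  s2 <- sort(kshell_decomposition(net2)$shell)
  expect_equal(s1, s2)
})
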