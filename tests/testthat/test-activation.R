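test_that("smoothing: identity at fwhm 0, constants preserved, translation-equivariant", {
  set.seed(1)
  arr <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4))
  expect_identical(smooth_volume(arr, 0, voxel_size_mm = 4), arr)

  const <- array(3.5, dim = c(6, 6, 3))
  expect_equal(smooth_volume(const, 4, voxel_size_mm = 4), const,
               tolerance = 1e-12)

  # shifting the input shifts the output (away from the boundary)
  sm <- smooth_volume(arr, 6, voxel_size_mm = 4)
  shifted <- array(0, dim = dim(arr))
  shifted[2:8, , ] <- arr[1:7, , ]
  sm_sh <- smooth_volume(shifted, 6, voxel_size_mm = 4)
  expect_equal(sm_sh[4:6, 3:6, 2:3], sm[3:5, 3:6, 2:3], tolerance = 1e-4)

  # FWHM 4 mm at 4 mm voxels -> Gaussian sd 4/(2*sqrt(2*log(2))) mm
  # ~ 0.425 voxels, checked on a point source via the neighbor ratio
  delta <- array(0, dim = c(9, 9, 9))
  delta[5, 5, 5] <- 1
  smd <- smooth_volume(delta, 4, voxel_size_mm = 4)
  sd_vox <- 4 / (2 * sqrt(2 * log(2))) / 4
  expect_equal(smd[6, 5, 5] / smd[5, 5, 5], exp(-1 / (2 * sd_vox^2)),
               tolerance = 1e-6)
})

test_that("activation statistics match the regressor by construction", {
  p <- task_paradigm(4, 20, 30, 2.5)
  reg <- hrf_regressor(p)
  nt <- n_frames(p)
  arr <- array(0, dim = c(2, 2, 1, nt))
  arr[1, 1, 1, ] <- reg
  arr[2, 1, 1, ] <- -reg
  set.seed(2)
  arr[1, 2, 1, ] <- rnorm(nt)
  arr[2, 2, 1, ] <- 7           # constant voxel
  scan <- subject_scan(arr, 4, p)
  st <- activation_statistics(scan, reg)
  expect_equal(st$r[1, 1, 1], 1)
  expect_lt(st$p[1, 1, 1], 1e-12)
  expect_equal(st$r[2, 1, 1], -1)
  expect_equal(st$r[2, 2, 1], 0)
  expect_equal(st$p[2, 2, 1], 1)
  expect_true(st$constant[2, 2, 1])
  expect_error(activation_statistics(scan, rep(1, nt)), "constant")
  expect_error(activation_statistics(scan, reg[-1]), "length")
})

test_that("voxel-level type-I rate is calibrated on pure noise", {
  nt <- 160
  nv <- 10000
  set.seed(42)
  arr <- array(rnorm(nv * nt), dim = c(100, 10, 10, nt))
  p <- task_paradigm(8, 20, 30, 2.5)
  scan <- subject_scan(arr, 4, p)
  st <- activation_statistics(scan, hrf_regressor(p))
  rate <- mean(st$p <= 0.001)
  expect_lt(abs(rate - 0.001), 3 * sqrt(0.001 * 0.999 / nv))
})

test_that("SD filter applies the fractional rule and flags degenerate means", {
  nt <- 80
  p <- task_paradigm(1, 20, 180, 2.5)
  arr <- array(0, dim = c(3, 1, 1, nt))
  arr[1, 1, 1, ] <- 100 + rnorm(nt) * 10   # SD/mean ~ 0.10 -> excluded
  arr[2, 1, 1, ] <- 100 + rnorm(nt) * 5    # SD/mean ~ 0.05 -> retained
  arr[3, 1, 1, ] <- rnorm(nt)              # mean ~ 0 -> excluded + warning
  scan <- subject_scan(arr, 4, p)
  expect_warning(keep <- sd_filter(scan, 0.08), "non-positive")
  expect_false(keep[1, 1, 1])
  expect_true(keep[2, 1, 1])
  expect_false(keep[3, 1, 1])
})

test_that("connected components respect the neighborhood definition", {
  mask <- array(FALSE, dim = c(8, 8, 4))
  mask[1:2, 1:2, 1] <- TRUE
  mask[6:7, 6:7, 3] <- TRUE
  expect_length(cluster_components(mask, 6), 2)

  # two blobs touching only at a corner
  corner <- array(FALSE, dim = c(6, 6, 2))
  corner[1:2, 1:2, 1] <- TRUE
  corner[3, 3, 1] <- TRUE
  expect_length(cluster_components(corner, 6), 2)
  expect_length(cluster_components(corner, 26), 1)

  expect_length(cluster_components(array(FALSE, dim = c(4, 4, 2))), 0)
})

test_that("components agree with an igraph flood-fill oracle", {
  set.seed(9)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:10) {
      dims <- c(7, 6, 4)
      mask <- array(runif(prod(dims)) < 0.35, dim = dims)
      comps <- cluster_components(mask, conn)
      # oracle: igraph components over the same adjacency
      idx <- which(mask)
      if (!length(idx)) {
        expect_length(comps, 0)
        next
      }
      co <- arrayInd(idx, dims)
      g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
      g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
      ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
      g <- g[ord <= c("6" = 1, "18" = 2, "26" = 3)[as.character(conn)], ]
      ed <- NULL
      for (k in seq_len(nrow(g))) {
        nb <- sweep(co, 2, as.numeric(g[k, ]), "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
          nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
        lin <- nb[ok, 1] + (nb[ok, 2] - 1) * dims[1] +
          (nb[ok, 3] - 1) * dims[1] * dims[2]
        hit <- match(lin, idx)
        src <- which(ok)[!is.na(hit)]
        ed <- rbind(ed, cbind(src, hit[!is.na(hit)]))
      }
      gr <- igraph::graph_from_edgelist(ed, directed = FALSE)
      gr <- igraph::add_vertices(gr, max(0, length(idx) - igraph::vcount(gr)))
      memb <- igraph::components(gr)$membership
      expect_equal(sort(lengths(comps), decreasing = TRUE),
                   sort(as.integer(table(memb)), decreasing = TRUE))
    }
  }
})

test_that("cluster-extent correction keeps planted signal, drops isolated voxels", {
  cfg <- mini_config(noise_sd = 1)
  s <- simulate_subject(cfg, subject_seed = 21)
  acfg <- analysis_config(n_null = 150, seed = 1)
  set.seed(31)
  am <- cluster_threshold(s$scan, acfg)
  planted <- which(s$labels$labels == 1L)
  found <- which(am$active)
  dice_best <- max(vapply(am$clusters, function(cl)
    2 * length(intersect(cl, planted)) / (length(cl) + length(planted)),
    numeric(1)))
  expect_gte(dice_best, 0.5)
  # all surviving clusters beat the null extent threshold
  expect_true(all(lengths(am$clusters) > am$extent_threshold))
  # active set is inside the voxelwise-threshold-and-SD mask
  expect_true(all(am$p[am$active] <= acfg$p_voxel))
  expect_true(all(am$sd_keep[am$active]))
})

test_that("suprathreshold mask shrinks monotonically with stricter p_voxel", {
  cfg <- mini_config()
  s <- simulate_subject(cfg, subject_seed = 4)
  acfg <- analysis_config(n_null = 120, seed = 1)
  set.seed(5)
  am <- cluster_threshold(s$scan, acfg)
  strict <- (am$p <= 1e-4) & am$sd_keep
  loose <- (am$p <= 1e-3) & am$sd_keep
  expect_true(all(!strict | loose))
})
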