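#' Planted active region specification
#'
#' Describes one spatially contiguous active region on the voxel grid,
#' either a cuboid (`origin` + `size`, 1-based voxel indices) or a sphere
#' (`center` + `radius` in voxels).
#'
#' @param name Region name, e.g. `"BA(L)"`.
#' @param label_id Positive integer anatomical label.
#' @param origin,size Integer 3-vectors defining a cuboid (used when
#'   `shape = "cuboid"`).
#' @param center,radius Sphere center (3-vector) and radius in voxels
#'   (used when `shape = "sphere"`).
#' @param beta Task response amplitude (non-negative; 0 = not task-driven).
#' @param within_coupling Amplitude of the region-shared latent signal
#'   (non-negative).
#' @param excluded Logical; `TRUE` marks regions whose activation is a
#'   paradigm-delivery artifact (e.g. visual cortex) to be discarded from
#'   network construction.
#' @param shape `"cuboid"` or `"sphere"`.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, label_id, origin = NULL, size = NULL,
                        center = NULL, radius = NULL, beta = 0,
                        within_coupling = 0, excluded = FALSE,
                        shape = c("cuboid", "sphere")) {
  shape <- match.arg(shape)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!is.finite(label_id) || label_id < 1 || label_id != round(label_id))
    stop("`label_id` must be a positive integer")
  if (!is.finite(beta) || beta < 0) stop("`beta` must be >= 0")
  if (!is.finite(within_coupling) || within_coupling < 0)
    stop("`within_coupling` must be >= 0")
  if (shape == "cuboid") {
    if (is.null(origin) || is.null(size) || length(origin) != 3 ||
        length(size) != 3 || any(size < 1) || any(origin < 1))
      stop("cuboid region needs integer 3-vectors `origin` (>= 1) and `size` (>= 1)")
  } else {
    if (is.null(center) || is.null(radius) || length(center) != 3 || radius <= 0)
      stop("sphere region needs `center` (3-vector) and `radius` > 0")
  }
  structure(list(name = name, label_id = as.integer(label_id), shape = shape,
                 origin = origin, size = size, center = center, radius = radius,
                 beta = beta, within_coupling = within_coupling,
                 excluded = isTRUE(excluded)),
            class = "region_spec")
}

region_voxels <- function(region, grid_shape) {
  if (region$shape == "cuboid") {
    hi <- region$origin + region$size - 1
    if (any(hi > grid_shape))
      stop("region '", region$name, "' extends outside the grid")
    g <- expand.grid(x = region$origin[1]:hi[1], y = region$origin[2]:hi[2],
                     z = region$origin[3]:hi[3])
  } else {
    r <- ceiling(region$radius)
    rng <- function(c, n) max(1, c - r):min(n, c + r)
    g <- expand.grid(x = rng(region$center[1], grid_shape[1]),
                     y = rng(region$center[2], grid_shape[2]),
                     z = rng(region$center[3], grid_shape[3]))
    d2 <- (g$x - region$center[1])^2 + (g$y - region$center[2])^2 +
      (g$z - region$center[3])^2
    g <- g[d2 <= region$radius^2, , drop = FALSE]
    if (nrow(g) == 0) stop("region '", region$name, "' is empty on this grid")
  }
  as.integer(g$x + (g$y - 1) * grid_shape[1] +
               (g$z - 1) * grid_shape[1] * grid_shape[2])
}

#' Canonical name for an unordered region pair
#'
#' Region-pair couplings are keyed `"regionA|regionB"` with the two names
#' in sorted order; this helper builds that key.
#'
#' @param a,b Region names.
#' @return Character scalar.
#' @export
canonical_pair <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Synthetic multi-subject BOLD configuration
#'
#' Defines the generative model for synthetic block-design BOLD data. Each
#' voxel time series is
#' `baseline + beta_r * s(t) + a_r * z_r(t) + sum_n c_rn * g_rn(t) + eps(t)`,
#' where `s(t)` is the hemodynamic-response-convolved task boxcar, `z_r` is
#' a unit-variance latent shared by all voxels of region `r`, `g_rn` is a
#' unit-variance latent shared by the coupled region pair `(r, n)`, and
#' `eps` is white noise with standard deviation `noise_sd`. Voxels outside
#' all regions carry `baseline + eps` only.
#'
#' @param grid_shape Integer 3-vector, voxels per axis.
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param paradigm A [task_paradigm()].
#' @param regions List of [region_spec()] objects; voxel sets must be
#'   pairwise disjoint and inside the grid.
#' @param between_coupling Named non-negative numeric vector of pair
#'   coupling amplitudes `c_mn`; names are `"regionA|regionB"` with the two
#'   region names in sorted order (see [canonical_pair()] convention:
#'   `sort()` then `paste(collapse = "|")`).
#' @param noise_sd White-noise standard deviation (> 0).
#' @param baseline Baseline signal intensity.
#' @param subject_jitter_sd Standard deviation (log scale) of the single
#'   lognormal per-subject gain factor applied to all betas and couplings
#'   (mean 1; 0 disables jitter).
#' @param hrf_peak_s,hrf_sd_s Hemodynamic kernel used for the planted task
#'   signal, see [hrf_kernel()].
#' @param seed Base integer seed recorded with the configuration.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape, voxel_size_mm = 4,
                             paradigm = task_paradigm(), regions = list(),
                             between_coupling = numeric(), noise_sd = 1,
                             baseline = 100, subject_jitter_sd = 0.1,
                             hrf_peak_s = 5, hrf_sd_s = 2.5, seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            all(grid_shape == round(grid_shape)))
  if (!is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be > 0")
  stopifnot(inherits(paradigm, "task_paradigm"))
  if (n_frames(paradigm) < 2) stop("paradigm must yield at least 2 time points")
  if (!is.finite(noise_sd) || noise_sd <= 0) stop("`noise_sd` must be > 0")
  if (!is.finite(subject_jitter_sd) || subject_jitter_sd < 0)
    stop("`subject_jitter_sd` must be >= 0")
  grid_shape <- as.integer(grid_shape)
  nms <- vapply(regions, function(r) r$name, character(1))
  if (anyDuplicated(nms)) stop("region names must be unique")
  ids <- vapply(regions, function(r) r$label_id, integer(1))
  if (anyDuplicated(ids)) stop("region label ids must be unique")
  vox <- lapply(regions, region_voxels, grid_shape = grid_shape)
  all_vox <- unlist(vox)
  if (anyDuplicated(all_vox)) {
    dup <- all_vox[duplicated(all_vox)][1]
    off <- nms[vapply(vox, function(v) dup %in% v, logical(1))]
    stop("regions overlap (", paste(off, collapse = ", "), ")")
  }
  if (length(between_coupling)) {
    if (is.null(names(between_coupling)) || any(!nzchar(names(between_coupling))))
      stop("`between_coupling` must be a named vector ('regionA|regionB')")
    if (any(!is.finite(between_coupling)) || any(between_coupling < 0))
      stop("coupling amplitudes must be finite and >= 0")
    for (nm in names(between_coupling)) {
      pr <- strsplit(nm, "|", fixed = TRUE)[[1]]
      if (length(pr) != 2 || !all(pr %in% nms))
        stop("coupling '", nm, "' does not name two known regions")
      if (nm != canonical_pair(pr[1], pr[2]))
        stop("coupling name '", nm, "' is not in canonical (sorted) order")
    }
    if (anyDuplicated(names(between_coupling)))
      stop("duplicate coupling names")
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 paradigm = paradigm, regions = regions,
                 between_coupling = between_coupling, noise_sd = noise_sd,
                 baseline = baseline, subject_jitter_sd = subject_jitter_sd,
                 hrf_peak_s = hrf_peak_s, hrf_sd_s = hrf_sd_s,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate one subject's 4D BOLD scan
#'
#' Draws one subject from a [synthetic_config()]: a single lognormal gain
#' factor (shared across all betas and couplings, preserving the planted
#' correlation structure), region and pair latents, and voxel noise.
#' Identical `(config, subject_seed)` yields bit-identical output.
#'
#' @param config A [synthetic_config()].
#' @param subject_seed Integer seed for this subject.
#' @param subject_id,group_id Identifier strings stored on the scan.
#' @param dropout_regions Character vector of region names that are *not*
#'   activated in this subject: their beta, within-coupling and all pair
#'   couplings are set to zero (latent draws are kept so the remaining
#'   regions' series are unchanged).
#' @return A list of class `synthetic_subject` with elements `scan`
#'   (a `subject_scan`), `labels` (a [label_map()]) and `truth` (planted
#'   parameters after gain and dropout, including the implied descending
#'   coupling ranking with ties recorded).
#' @export
simulate_subject <- function(config, subject_seed, subject_id = "s1",
                             group_id = "g1", dropout_regions = character()) {
  stopifnot(inherits(config, "synthetic_config"))
  bad <- setdiff(dropout_regions, vapply(config$regions, `[[`, "", "name"))
  if (length(bad)) stop("unknown dropout region(s): ", paste(bad, collapse = ", "))
  nt <- n_frames(config$paradigm)
  nvox <- prod(config$grid_shape)
  s <- hrf_regressor(config$paradigm, config$hrf_peak_s, config$hrf_sd_s)

  set.seed(as.integer(subject_seed))
  gain <- if (config$subject_jitter_sd > 0)
    stats::rlnorm(1, meanlog = -config$subject_jitter_sd^2 / 2,
                  sdlog = config$subject_jitter_sd) else 1

  nms <- vapply(config$regions, `[[`, "", "name")
  z <- matrix(stats::rnorm(nt * length(nms)), nrow = nt,
              dimnames = list(NULL, nms))
  cpl <- config$between_coupling
  if (length(cpl)) cpl <- cpl[order(names(cpl))]
  g <- if (length(cpl))
    matrix(stats::rnorm(nt * length(cpl)), nrow = nt,
           dimnames = list(NULL, names(cpl))) else
    matrix(numeric(0), nrow = nt, ncol = 0)
  # Orthonormalize the latent basis in-sample (against the intercept, the
  # task regressor and each other; unit sample variance). The latents are
  # unit-variance by model definition; realizing that exactly per draw
  # keeps the planted block correlation structure free of realized
  # second-moment drift at finite series length.
  lat <- cbind(z, g)
  if (ncol(lat)) {
    base <- if (stats::sd(s) > 0) cbind(1, s) else matrix(1, nt, 1)
    qb <- qr(cbind(base, lat))
    if (qb$rank < ncol(base) + ncol(lat))
      stop("latent basis is rank deficient; paradigm too short for the ",
           "number of regions and couplings")
    Q <- qr.Q(qb)[, (ncol(base) + 1):(ncol(base) + ncol(lat)), drop = FALSE]
    lat <- Q * sqrt(nt - 1)
    z <- lat[, seq_along(nms), drop = FALSE]
    colnames(z) <- nms
    if (length(cpl)) {
      g <- lat[, length(nms) + seq_along(cpl), drop = FALSE]
      colnames(g) <- names(cpl)
    }
  }
  data <- matrix(stats::rnorm(nt * nvox, sd = config$noise_sd), nrow = nt)
  data <- data + config$baseline

  labels <- array(0L, dim = config$grid_shape)
  beta_eff <- a_eff <- stats::setNames(numeric(length(nms)), nms)
  cpl_eff <- gain * cpl
  for (nm in names(cpl_eff)) {
    pr <- strsplit(nm, "|", fixed = TRUE)[[1]]
    if (any(pr %in% dropout_regions)) cpl_eff[nm] <- 0
  }
  for (i in seq_along(config$regions)) {
    r <- config$regions[[i]]
    idx <- region_voxels(r, config$grid_shape)
    labels[idx] <- r$label_id
    if (r$name %in% dropout_regions) next
    beta_eff[r$name] <- gain * r$beta
    a_eff[r$name] <- gain * r$within_coupling
    sig <- beta_eff[r$name] * s + a_eff[r$name] * z[, r$name]
    for (nm in names(cpl_eff)) {
      if (cpl_eff[nm] == 0) next
      pr <- strsplit(nm, "|", fixed = TRUE)[[1]]
      if (r$name %in% pr) sig <- sig + cpl_eff[nm] * g[, nm]
    }
    data[, idx] <- data[, idx] + sig
  }

  scan <- subject_scan(array(t(data), dim = c(config$grid_shape, nt)),
                       voxel_size_mm = config$voxel_size_mm,
                       paradigm = config$paradigm,
                       subject_id = subject_id, group_id = group_id)
  lm <- label_map(labels,
                  names = stats::setNames(
                    nms, vapply(config$regions, `[[`, 1L, "label_id")),
                  excluded = vapply(config$regions, `[[`, 1L, "label_id")[
                    vapply(config$regions, `[[`, TRUE, "excluded")])
  truth <- list(subject_id = subject_id, group_id = group_id,
                subject_seed = as.integer(subject_seed), gain = gain,
                dropout_regions = dropout_regions,
                regions = data.frame(
                  region = nms,
                  label_id = vapply(config$regions, `[[`, 1L, "label_id"),
                  size = vapply(config$regions, function(r)
                    length(region_voxels(r, config$grid_shape)), integer(1)),
                  beta = unname(beta_eff), within_coupling = unname(a_eff),
                  excluded = vapply(config$regions, `[[`, TRUE, "excluded"),
                  stringsAsFactors = FALSE),
                couplings = cpl_eff,
                coupling_ranking = coupling_ranking(cpl_eff))
  structure(list(scan = scan, labels = lm, truth = truth),
            class = "synthetic_subject")
}

coupling_ranking <- function(couplings) {
  if (!length(couplings)) return(data.frame(pair = character(), value = numeric(),
                                            rank = integer(), tie = logical()))
  ord <- order(-couplings, names(couplings))
  v <- couplings[ord]
  rk <- match(-v, sort(unique(-v)))
  data.frame(pair = names(v), value = unname(v), rank = rk,
             tie = duplicated(rk) | duplicated(rk, fromLast = TRUE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a group of subjects
#'
#' Per-subject seeds are derived deterministically from `group_seed`;
#' subjects share the region geometry and coupling structure and differ by
#' their gain factor, latent draws, noise, and any planted dropout.
#'
#' @inheritParams simulate_subject
#' @param n_subjects Number of subjects (>= 1).
#' @param group_seed Integer seed for the group.
#' @param region_dropout Named list mapping a region name to the integer
#'   subject indices in which that region is not activated, e.g.
#'   `list("WA(L)" = c(7, 8))` plants the V structure in 6 of 8 subjects.
#' @return A list of class `synthetic_group`: `subjects` (list of
#'   `synthetic_subject`), `group_id`, `truth` (seeds and per-subject
#'   dropout table).
#' @export
simulate_group <- function(config, n_subjects = 8, group_seed = 1L,
                           group_id = "g1", region_dropout = list()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.finite(n_subjects) || n_subjects < 1 ||
      n_subjects != round(n_subjects))
    stop("`n_subjects` must be a positive integer")
  if (length(region_dropout)) {
    bad <- setdiff(names(region_dropout),
                   vapply(config$regions, `[[`, "", "name"))
    if (length(bad)) stop("unknown region(s) in `region_dropout`: ",
                          paste(bad, collapse = ", "))
    if (any(unlist(region_dropout) < 1 | unlist(region_dropout) > n_subjects))
      stop("`region_dropout` subject indices out of range")
  }
  set.seed(as.integer(group_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    drop_i <- names(region_dropout)[vapply(region_dropout,
                                           function(v) i %in% v, logical(1))]
    subjects[[i]] <- simulate_subject(
      config, subject_seed = seeds[i],
      subject_id = sprintf("%s_s%02d", group_id, i), group_id = group_id,
      dropout_regions = drop_i)
  }
  structure(list(subjects = subjects, group_id = group_id,
                 truth = list(group_seed = as.integer(group_seed),
                              subject_seeds = seeds,
                              region_dropout = region_dropout,
                              config = config)),
            class = "synthetic_group")
}

#' Geometric coupling-ladder configuration for hierarchy recovery
#'
#' A variant of [language_cohort_config()] whose five named couplings form
#' a geometric ladder with a fixed adjacent ratio (default 1.5, i.e.
#' well-separated planted couplings), for parameter-recovery experiments:
#' the recovered common-network link ranking should equal the planted
#' order A > B > C > D > E. The per-region within-coupling amplitudes
#' solve the same equal-variance budget as the cohort defaults; because
#' the ladder reaches much weaker couplings than the dense-triangle
#' defaults, recovery experiments with this configuration are designed for
#' a voxel-link threshold of `corr_threshold = 0.5` (reported, as all
#' threshold-sensitive results, conditional on theta).
#'
#' @param ratio Adjacent coupling ratio (>= 1, default 1.5).
#' @param c_top Strongest coupling amplitude (link A), default 1.149.
#' @param seed Base seed recorded in the configuration.
#' @return A [synthetic_config()].
#' @export
hierarchy_ladder_config <- function(ratio = 1.5, c_top = 1.149, seed = 1L) {
  if (!is.finite(ratio) || ratio < 1) stop("`ratio` must be >= 1")
  cl <- c_top / ratio^(0:4)
  base <- language_cohort_config(seed = seed)
  regions <- base$config$regions
  cc2 <- cl^2
  # per-region variance budget: beta^2 var(s) + a^2 + sum c^2 + noise^2
  # held equal across regions (see the package vignette)
  v <- 2.84
  beta <- sqrt(v / 0.188)
  budget <- 5.67
  sums <- c("pre-SMA" = cc2[2] + cc2[3], "BA(L)" = cc2[1] + cc2[3] + cc2[4],
            "v-preMA(L)" = cc2[1] + cc2[2] + cc2[5],
            "WA(L)" = cc2[4] + cc2[5], "a-MFG(L)" = 0, "SupraMG(L)" = 0,
            "Visual" = 0)
  for (i in seq_along(regions)) {
    nm <- regions[[i]]$name
    regions[[i]]$beta <- beta
    a2 <- budget - v - sums[[nm]]
    if (a2 < 0) stop("coupling ladder exceeds the variance budget for ", nm)
    regions[[i]]$within_coupling <- sqrt(a2)
  }
  coupling <- cl
  names(coupling) <- names(base$config$between_coupling)
  synthetic_config(grid_shape = base$config$grid_shape,
                   voxel_size_mm = base$config$voxel_size_mm,
                   paradigm = base$config$paradigm, regions = regions,
                   between_coupling = coupling, noise_sd = 1, baseline = 100,
                   subject_jitter_sd = base$config$subject_jitter_sd,
                   seed = seed)
}

#' Matched configurations for the WA-attachment contrast experiment
#'
#' Two cohort configurations that differ only in the strength of the
#' Wernicke-area couplings (links D and E): `"strong"` sets them to the
#' maximum the per-region variance budget allows, `"zero"` removes them.
#' Relative to [language_cohort_config()], the task share is raised
#' (beta ~ 4.5) so that the triangle couplings saturate: the three core
#' modules then occupy the maximum shell exactly, in both arms, and any
#' shell-occupancy difference between matched groups is carried by WA
#' alone. Simulating both arms with the same group seed yields a paired
#' comparison in which everything except the WA attachment is shared.
#'
#' @param wa_coupling `"strong"` or `"zero"`.
#' @param seed Base seed recorded in the configuration.
#' @return A [synthetic_config()].
#' @export
wa_contrast_config <- function(wa_coupling = c("strong", "zero"), seed = 1L) {
  wa_coupling <- match.arg(wa_coupling)
  base <- language_cohort_config(seed = seed)$config
  v <- 3.4                     # task variance: floor correlation ~ 0.54,
                               # below the link threshold on the
                               # post-smoothing effective scale
  beta <- sqrt(v / 0.188)
  budget <- 5.67 - v           # per-region coupling + within budget
  xA <- 4.158 - v              # saturates the triangle links (rho ~ 0.66)
  xD <- budget - 2 * xA        # all remaining slack to the WA links
  # the zero arm reallocates every removed coupling share to the
  # region-private latent of the region that carried it, so all region
  # variances (hence all remaining correlations, including the task
  # floor) are matched exactly between the arms
  comp <- if (wa_coupling == "strong") 0 else xD
  a2 <- c("pre-SMA" = budget - 2 * xA, "BA(L)" = comp,
          "v-preMA(L)" = comp, "WA(L)" = budget - 2 * xD + 2 * comp,
          "a-MFG(L)" = budget, "SupraMG(L)" = budget, "Visual" = budget)
  regions <- base$regions
  for (i in seq_along(regions)) {
    regions[[i]]$beta <- beta
    regions[[i]]$within_coupling <- sqrt(a2[[regions[[i]]$name]])
  }
  wa <- if (wa_coupling == "strong") sqrt(xD) else 0
  cc <- c(sqrt(xA), sqrt(xA), sqrt(xA), wa, wa)
  names(cc) <- names(base$between_coupling)
  synthetic_config(grid_shape = base$grid_shape,
                   voxel_size_mm = base$voxel_size_mm,
                   paradigm = base$paradigm, regions = regions,
                   between_coupling = cc, noise_sd = 1, baseline = 100,
                   subject_jitter_sd = base$subject_jitter_sd, seed = seed)
}

#' Study-conditions synthetic cohort configuration
#'
#' The default synthetic emulation of the block-design language-task study:
#' a 24 x 24 x 12 grid of 4 mm voxels, 8 epochs of 20 s task + 30 s rest at
#' TR 2.5 s (160 frames), seven planted regions (the pre-SMA / BA(L) /
#' v-preMA(L) triangle, WA(L), two peripheral regions, and an excluded
#' visual region), a dense triangle coupling ladder `A > B > C`, weak
#' WA couplings `D > E`, and group-wise WA/peripheral dropout that plants
#' the V-structure prevalences 6/8, 4/8 and 8/8.
#'
#' The amplitudes were chosen from the generative model's closed form so
#' that (at theta = 0.6 and 160 frames) intra-region correlations are far
#' above threshold, triangle couplings all express dense inter-region
#' links with the planted ordering, WA attaches weakly, and uncoupled
#' region pairs stay essentially unlinked; see the package vignette.
#'
#' @param subject_jitter_sd Per-subject lognormal gain SD (default 0.1).
#' @param seed Base seed recorded in the configuration.
#' @return A list with elements `config` (a [synthetic_config()]) and
#'   `groups` (per-group `n_subjects` and `region_dropout` lists, keyed
#'   `monolingual`, `bilingual_english`, `bilingual_spanish`).
#' @export
language_cohort_config <- function(subject_jitter_sd = 0.1, seed = 1L) {
  regions <- list(
    region_spec("pre-SMA",     1L, origin = c(10,  4, 8), size = c(3, 4, 3),
                beta = 4.03, within_coupling = 0.938),
    region_spec("BA(L)",       2L, origin = c(4,  10, 5), size = c(4, 3, 3),
                beta = 4.03, within_coupling = 0.345),
    region_spec("v-preMA(L)",  3L, origin = c(10, 15, 6), size = c(4, 3, 3),
                beta = 4.03, within_coupling = 0.224),
    region_spec("WA(L)",       4L, origin = c(18, 16, 5), size = c(5, 2, 2),
                beta = 4.03, within_coupling = 1.229),
    region_spec("a-MFG(L)",    5L, origin = c(4,  18, 9), size = c(3, 3, 2),
                beta = 4.03, within_coupling = 1.619),
    region_spec("SupraMG(L)",  6L, origin = c(17,  9, 8), size = c(3, 3, 2),
                beta = 4.03, within_coupling = 1.619),
    region_spec("Visual",      7L, origin = c(19,  2, 3), size = c(4, 4, 2),
                beta = 4.03, within_coupling = 1.619, excluded = TRUE))
  coupling <- c(1.053, 0.975, 0.891, 0.775, 0.714)
  names(coupling) <- c(canonical_pair("BA(L)", "v-preMA(L)"),      # A
                       canonical_pair("pre-SMA", "v-preMA(L)"),    # B
                       canonical_pair("pre-SMA", "BA(L)"),         # C
                       canonical_pair("BA(L)", "WA(L)"),           # D
                       canonical_pair("v-preMA(L)", "WA(L)"))      # E
  cfg <- synthetic_config(
    grid_shape = c(24, 24, 12), voxel_size_mm = 4,
    paradigm = task_paradigm(8, 20, 30, 2.5),
    regions = regions, between_coupling = coupling,
    noise_sd = 1, baseline = 100, subject_jitter_sd = subject_jitter_sd,
    seed = seed)
  groups <- list(
    monolingual = list(
      n_subjects = 8,
      region_dropout = list("WA(L)" = c(7, 8), "a-MFG(L)" = c(2, 4, 6),
                            "SupraMG(L)" = c(3, 5))),
    bilingual_english = list(
      n_subjects = 8,
      region_dropout = list("WA(L)" = c(2, 4, 6, 8), "a-MFG(L)" = c(1, 5, 7),
                            "SupraMG(L)" = c(4, 6))),
    bilingual_spanish = list(
      n_subjects = 8,
      region_dropout = list("a-MFG(L)" = c(3, 6), "SupraMG(L)" = c(2, 7))))
  list(config = cfg, groups = groups)
}
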