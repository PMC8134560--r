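#' Full pipeline configuration
#'
#' Bundles the analysis configuration with either a synthetic cohort
#' specification (a [synthetic_config()] plus per-group subject counts,
#' seeds and planted dropout) or a listing of input NIfTI files per group.
#'
#' @param analysis An [analysis_config()].
#' @param synthetic A [synthetic_config()], when the cohort is simulated.
#' @param groups Named list; per group either
#'   `list(n_subjects =, group_seed =, region_dropout =)` (synthetic mode)
#'   or `list(scans = c(paths), labels = path or c(paths))` (file mode).
#' @param roles Role mapping for structure detection, see
#'   [detect_structures()].
#' @param modules Modules for the occupancy histograms (default: the four
#'   role regions).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(analysis, synthetic = NULL, groups,
                            roles = default_roles(), modules = NULL) {
  stopifnot(inherits(analysis, "analysis_config"))
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  if (!length(groups) || is.null(names(groups)))
    stop("`groups` must be a named list")
  if (is.null(modules)) modules <- unname(roles)
  structure(list(analysis = analysis, synthetic = synthetic, groups = groups,
                 roles = roles, modules = modules),
            class = "pipeline_config")
}

stage_msg <- function(verbose, ...) if (verbose) message(...)

#' Run the complete analysis pipeline
#'
#' Executes simulate (optional) -> activation mapping -> network
#' construction -> common networks and structures -> k-shell occupancy ->
#' group SSE, writing each stage's outputs before the next starts, plus a
#' run manifest with seeds, the configuration snapshot and checksums of
#' every output. All randomness (simulation and surrogate nulls) derives
#' from the seeds recorded in the manifest, so
#' [rerun_from_manifest()] reproduces every table byte-identically.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param write_volumes Also export activation maps (r, p, mask) and
#'   synthetic scans/labels as NIfTI (default `FALSE`; tables are always
#'   written).
#' @param verbose Emit per-stage messages (default `TRUE`).
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, write_volumes = FALSE,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  acfg <- config$analysis
  if (is.null(acfg$seed)) {
    acfg$seed <- 1L
    config$analysis <- acfg
  }
  hash <- config_hash(list(analysis = unclass(acfg),
                           synthetic = if (!is.null(config$synthetic))
                             serialize_synthetic_config(config$synthetic),
                           groups = config$groups, roles = config$roles,
                           modules = config$modules))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("activation", "networks", "common", "kshell"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)

  outputs <- character()
  keep <- function(p) { outputs <<- c(outputs, p); p }

  synthetic_mode <- !is.null(config$synthetic)
  group_names <- names(config$groups)
  region_nets <- list()
  assignments <- list()
  subject_seeds <- list()

  for (gi in seq_along(config$groups)) {
    gname <- group_names[gi]
    gspec <- config$groups[[gi]]
    stage_msg(verbose, "group '", gname, "': preparing subjects")
    if (synthetic_mode) {
      gseed <- gspec$group_seed %||% (acfg$seed + 101L * gi)
      config$groups[[gi]]$group_seed <- gseed
      grp <- simulate_group(config$synthetic,
                            n_subjects = gspec$n_subjects,
                            group_seed = gseed, group_id = gname,
                            region_dropout = gspec$region_dropout %||% list())
      scans <- lapply(grp$subjects, `[[`, "scan")
      labs <- lapply(grp$subjects, `[[`, "labels")
      subject_seeds[[gname]] <- list(group_seed = gseed,
                                     seeds = grp$truth$subject_seeds)
      if (write_volumes) {
        for (k in seq_along(scans)) {
          keep(write_volume(scans[[k]], file.path(
            out_dir, sprintf("%s_s%02d_bold.nii", gname, k))))
          keep(write_volume(labs[[k]]$labels, file.path(
            out_dir, sprintf("%s_s%02d_labels.nii", gname, k)),
            voxel_size_mm = config$synthetic$voxel_size_mm))
        }
      }
    } else {
      if (is.null(gspec$scans)) stop("group '", gname, "' lists no scans")
      scans <- lapply(seq_along(gspec$scans), function(k)
        read_scan(gspec$scans[k], paradigm = gspec$paradigm,
                  subject_id = sprintf("%s_s%02d", gname, k),
                  group_id = gname))
      lab_paths <- rep_len(gspec$labels, length(scans))
      labs <- lapply(lab_paths, read_label_volume, names = gspec$label_names,
                     excluded = gspec$label_excluded %||% integer())
    }

    gnets <- list()
    gassign <- list()
    for (k in seq_along(scans)) {
      sid <- sprintf("%s_s%02d", gname, k)
      set.seed(acfg$seed + 7919L * gi + k)  # surrogate-null stream
      res <- subject_network(scans[[k]], labs[[k]], acfg)
      keep(write_tsv(res$amap$cluster_table,
                     file.path(out_dir, "activation",
                               paste0(sid, "_clusters.tsv")), hash))
      if (write_volumes) {
        base <- file.path(out_dir, "activation", sid)
        keep(write_volume(res$amap$r, paste0(base, "_r.nii"),
                          voxel_size_mm = scans[[k]]$voxel_size_mm))
        keep(write_volume(res$amap$p, paste0(base, "_p.nii"),
                          voxel_size_mm = scans[[k]]$voxel_size_mm))
        keep(write_volume(array(as.numeric(res$amap$active),
                                dim = dim(res$amap$active)),
                          paste0(base, "_mask.nii"),
                          voxel_size_mm = scans[[k]]$voxel_size_mm))
      }
      if (is.null(res$voxel_net)) {
        stage_msg(verbose, "  ", sid, ": fewer than 2 active voxels; skipped")
        next
      }
      nbase <- file.path(out_dir, "networks", sid)
      keep(write_tsv(res$nodes, paste0(nbase, "_nodes.tsv"), hash))
      keep(write_tsv(res$voxel_net$edges, paste0(nbase, "_voxel_edges.tsv"),
                     hash))
      keep(write_tsv(res$froi_net$edges, paste0(nbase, "_froi_edges.tsv"),
                     hash))
      keep(write_graphml(res$froi_net, paste0(nbase, "_froi.graphml")))
      gnets[[sid]] <- res$region_net
      sa <- kshell_decomposition(res$voxel_net)
      gassign[[sid]] <- sa
      keep(write_tsv(data.frame(subject = sid,
                                voxel = res$nodes$index,
                                module = res$nodes$region,
                                k_s = sa$shell, k_max = sa$k_max,
                                normalized = sa$shell / sa$k_max),
                     paste0(file.path(out_dir, "kshell", sid), "_shells.tsv"),
                     hash))
    }
    region_nets[[gname]] <- gnets
    assignments[[gname]] <- gassign
  }

  stage_msg(verbose, "common networks and structures")
  commons <- list()
  for (gname in group_names) {
    nets <- region_nets[[gname]]
    if (!length(nets)) next
    cn <- build_common_network(nets, tau = acfg$common_retention,
                               group = gname)
    commons[[gname]] <- cn
    keep(write_tsv(cn$edges, file.path(out_dir, "common",
                                       paste0(gname, "_common.tsv")), hash))
    sr <- detect_structures(nets, roles = config$roles, group = gname)
    sj <- file.path(out_dir, "common", paste0(gname, "_structures.json"))
    jsonlite::write_json(
      list(group = gname, N = sr$N, triangle_count = sr$triangle_count,
           triangle_fraction = sr$triangle_fraction, v_count = sr$v_count,
           v_fraction = sr$v_fraction, per_subject = sr$per_subject,
           config = hash),
      sj, auto_unbox = TRUE, digits = NA)
    keep(sj)
    keep(write_tsv(rank_links(cn, named_links(config$roles)),
                   file.path(out_dir, "common",
                             paste0(gname, "_hierarchy.tsv")), hash))
  }

  stage_msg(verbose, "k-shell occupancy and SSE")
  hists <- list()
  for (gname in group_names) {
    if (!length(assignments[[gname]])) next
    hists[[gname]] <- occupancy_histogram(assignments[[gname]], group = gname,
                                          n_bins = acfg$n_bins,
                                          modules = config$modules)
  }
  if (length(hists)) {
    hj <- file.path(out_dir, "kshell", "histograms.json")
    jsonlite::write_json(
      list(config = hash, n_bins = acfg$n_bins,
           normalization = "per (module, group) fractions",
           groups = lapply(hists, function(h)
             lapply(h$modules, function(m)
               if (is.null(m)) NULL else m[c("mass", "counts", "n",
                                             "n_isolated")]))),
      hj, auto_unbox = TRUE, digits = NA, null = "null")
    keep(hj)
    if (length(hists) >= 2)
      keep(write_tsv(sse_between_groups(hists),
                     file.path(out_dir, "kshell", "sse.tsv"), hash))
  }

  manifest <- list(
    package = "flnet",
    version = as.character(utils::packageVersion("flnet")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = hash,
    analysis = unclass(acfg),
    synthetic = if (synthetic_mode)
      serialize_synthetic_config(config$synthetic),
    groups = config$groups, roles = as.list(config$roles),
    modules = config$modules, seeds = subject_seeds,
    outputs = data.frame(
      path = vapply(unlist(outputs), function(p)
        substring(p, nchar(out_dir) + 2), "", USE.NAMES = FALSE),
      md5 = unname(tools::md5sum(unlist(outputs)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  stage_msg(verbose, "done: ", length(outputs), " output file(s) in ", out_dir)
  invisible(manifest)
}

#' Re-run a pipeline from its manifest
#'
#' Reconstructs the configuration recorded in a run manifest and executes
#' the pipeline again; given the same package version, every table is
#' reproduced byte-identically.
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param out_dir Output directory for the re-run.
#' @param verbose Passed to [run_pipeline()].
#' @return The new manifest, invisibly.
#' @export
rerun_from_manifest <- function(manifest_path, out_dir, verbose = TRUE) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  acfg <- do.call(analysis_config, m$analysis)
  syn <- if (!is.null(m$synthetic)) deserialize_synthetic_config(m$synthetic)
  groups <- lapply(m$groups, function(g) {
    if (length(g$region_dropout))
      g$region_dropout <- lapply(g$region_dropout, function(v) unlist(v))
    else g$region_dropout <- NULL
    g
  })
  cfg <- pipeline_config(analysis = acfg, synthetic = syn, groups = groups,
                         roles = unlist(m$roles), modules = unlist(m$modules))
  run_pipeline(cfg, out_dir, verbose = verbose)
}
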