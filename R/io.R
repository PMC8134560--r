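#' Read a 4D BOLD scan from NIfTI
#'
#' @param path NIfTI file (4D).
#' @param paradigm The [task_paradigm()] the scan was acquired under; the
#'   file's time dimension must match.
#' @param subject_id,group_id Identifier strings.
#' @param voxel_size_mm Optional override; default taken from the header.
#' @return A [subject_scan()].
#' @export
read_scan <- function(path, paradigm, subject_id = "s1", group_id = "g1",
                      voxel_size_mm = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4)
    stop("expected a 4D scan, got ", length(d), "D: ", path)
  if (is.null(voxel_size_mm)) {
    pd <- attr(img, "pixdim")
    if (is.null(pd)) pd <- RNifti::pixdim(img)
    voxel_size_mm <- pd[1]
  }
  subject_scan(array(as.numeric(img), dim = d), voxel_size_mm = voxel_size_mm,
               paradigm = paradigm, subject_id = subject_id,
               group_id = group_id)
}

#' Read an anatomical label volume from NIfTI
#'
#' @param path NIfTI file (3D, integer labels).
#' @param names,excluded Name table and excluded ids, see [label_map()].
#' @return A [label_map()].
#' @export
read_label_volume <- function(path, names, excluded = integer()) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3)
    stop("expected a 3D label volume, got ", length(d), "D: ", path)
  label_map(array(as.integer(img), dim = d), names = names,
            excluded = excluded)
}

#' Write a volume (3D array, 4D array or subject_scan) as NIfTI
#'
#' Uncompressed `.nii` output; grid shape, voxel size and values round-trip
#' losslessly through [read_scan()] / [read_label_volume()].
#'
#' @param x Array or [subject_scan()].
#' @param path Output path (`.nii`).
#' @param voxel_size_mm Voxel size for bare arrays.
#' @param tr_s Optional TR stored in the time pixdim slot of 4D images.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_size_mm = 1, tr_s = NULL) {
  if (inherits(x, "subject_scan")) {
    tr_s <- x$paradigm$tr_s
    voxel_size_mm <- x$voxel_size_mm
    x <- x$data
  }
  nd <- length(dim(x))
  pd <- c(rep(voxel_size_mm, 3), if (nd == 4) (tr_s %||% 1))
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data.frame as a tab-separated table
#'
#' Plain deterministic TSV (no quoting, no row names); the configuration
#' hash, when given, is stored in a `# config:` header line so outputs from
#' different thresholds are never mixed silently.
#'
#' @param x data.frame.
#' @param path Output path.
#' @param cfg_hash Optional configuration hash to stamp.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, cfg_hash = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(cfg_hash)) writeLines(paste0("# config: ", cfg_hash), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_tsv()]
#' @param path File path.
#' @return data.frame; attribute `config_hash` if the stamp is present.
#' @export
read_tsv <- function(path) {
  first <- readLines(path, n = 1)
  hash <- NULL
  if (startsWith(first, "# config: ")) hash <- sub("^# config: ", "", first)
  out <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  attr(out, "config_hash") <- hash
  out
}

#' Export an fROI network as GraphML
#'
#' @param fnet A [froi_weights()] network.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(fnet, path) {
  stopifnot(inherits(fnet, "froi_network"))
  g <- igraph::graph_from_data_frame(
    fnet$edges[, c("froi_i", "froi_j", "n_cross", "W")],
    directed = FALSE,
    vertices = fnet$nodes[, c("froi", "region", "size")])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

serialize_synthetic_config <- function(config) {
  list(grid_shape = config$grid_shape, voxel_size_mm = config$voxel_size_mm,
       paradigm = unclass(config$paradigm),
       regions = lapply(config$regions, unclass),
       between_coupling = as.list(config$between_coupling),
       noise_sd = config$noise_sd, baseline = config$baseline,
       subject_jitter_sd = config$subject_jitter_sd,
       hrf_peak_s = config$hrf_peak_s, hrf_sd_s = config$hrf_sd_s,
       seed = config$seed)
}

deserialize_synthetic_config <- function(x) {
  par <- do.call(task_paradigm, x$paradigm)
  regions <- lapply(x$regions, function(r) {
    region_spec(name = r$name, label_id = r$label_id, shape = r$shape,
                origin = unlist(r$origin), size = unlist(r$size),
                center = unlist(r$center), radius = r$radius,
                beta = r$beta, within_coupling = r$within_coupling,
                excluded = r$excluded)
  })
  bc <- unlist(x$between_coupling)
  if (is.null(bc)) bc <- numeric()
  synthetic_config(grid_shape = unlist(x$grid_shape),
                   voxel_size_mm = x$voxel_size_mm, paradigm = par,
                   regions = regions, between_coupling = bc,
                   noise_sd = x$noise_sd, baseline = x$baseline,
                   subject_jitter_sd = x$subject_jitter_sd,
                   hrf_peak_s = x$hrf_peak_s, hrf_sd_s = x$hrf_sd_s,
                   seed = x$seed)
}

#' Write / read a synthetic configuration as JSON
#' @param config A [synthetic_config()].
#' @param path File path.
#' @return `read_synthetic_config` returns a `synthetic_config`.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  jsonlite::write_json(serialize_synthetic_config(config), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  deserialize_synthetic_config(jsonlite::read_json(path,
                                                   simplifyVector = FALSE))
}
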