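#' A subject's 4D BOLD scan
#'
#' @param data 4D numeric array `(x, y, z, time)`; all values finite and
#'   the time dimension must equal the paradigm length in TRs.
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param paradigm A [task_paradigm()].
#' @param subject_id,group_id Identifier strings.
#' @return An object of class `subject_scan`.
#' @export
subject_scan <- function(data, voxel_size_mm, paradigm,
                         subject_id = "s1", group_id = "g1") {
  if (!is.array(data) || length(dim(data)) != 4)
    stop("`data` must be a 4D array (x, y, z, time)")
  if (!all(is.finite(data))) stop("scan contains non-finite values")
  stopifnot(inherits(paradigm, "task_paradigm"))
  if (dim(data)[4] != n_frames(paradigm))
    stop("time dimension (", dim(data)[4], ") does not match the paradigm (",
         n_frames(paradigm), " frames)")
  if (!is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be > 0")
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 paradigm = paradigm, subject_id = subject_id,
                 group_id = group_id),
            class = "subject_scan")
}

#' @export
print.subject_scan <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<subject_scan %s/%s> grid %dx%dx%d, %d frames, voxel %.3g mm\n",
              x$group_id, x$subject_id, d[1], d[2], d[3], d[4],
              x$voxel_size_mm))
  invisible(x)
}

scan_matrix <- function(scan) {
  d <- dim(scan$data)
  matrix(scan$data, nrow = prod(d[1:3]), ncol = d[4])
}

#' Anatomical label volume
#'
#' @param labels 3D integer array; 0 is background, every other label must
#'   appear in `names`.
#' @param names Named character vector mapping `label_id` (names of the
#'   vector, coercible to integer) to region name.
#' @param excluded Integer vector of label ids to discard from network
#'   construction (e.g. visual cortex).
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, names, excluded = integer()) {
  if (!is.array(labels) || length(dim(labels)) != 3)
    stop("`labels` must be a 3D array")
  labels <- array(as.integer(labels), dim = dim(labels))
  ids <- sort(unique(labels[labels != 0L]))
  known <- as.integer(base::names(names))
  if (any(is.na(known))) stop("names of `names` must be label ids")
  missing <- setdiff(ids, known)
  if (length(missing))
    stop("label id(s) without a region name: ", paste(missing, collapse = ", "))
  excluded <- as.integer(excluded)
  if (length(setdiff(excluded, known)))
    stop("excluded label id(s) not present in the name table")
  structure(list(labels = labels, names = names, excluded = excluded),
            class = "label_map")
}

region_name <- function(map, id) {
  out <- rep(NA_character_, length(id))
  hit <- match(as.character(id), names(map$names))
  out[!is.na(hit)] <- unname(map$names[hit[!is.na(hit)]])
  out
}
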