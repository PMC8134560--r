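#' Assign active voxels to functional regions of interest
#'
#' Partitions the active voxels of an activation map into fROIs: connected
#' components of (active voxels within a single anatomical label). Voxels
#' in excluded regions (e.g. visual cortex) are dropped entirely; active
#' voxels on the background label are kept in flagged "unlabeled" fROIs so
#' no active signal disappears silently. A component spanning two labels is
#' split into one fROI per label.
#'
#' @param amap An [cluster_threshold()] activation map (or any object with
#'   a logical 3D `active` array).
#' @param labels A [label_map()] on the same grid.
#' @param connectivity Voxel neighborhood (6, 18, 26), default 6.
#' @return A data.frame of active nodes: `node` (1..n), `index` (linear
#'   voxel index), `x`, `y`, `z` (0-based grid coordinates), `label_id`,
#'   `region`, `froi` (fROI identifier, `"region#k"`), and `unlabeled`
#'   flag. Attribute `n_excluded` counts dropped excluded-region voxels.
#' @export
label_frois <- function(amap, labels, connectivity = 6) {
  stopifnot(inherits(labels, "label_map"))
  active <- amap$active
  if (!identical(dim(active), dim(labels$labels)))
    stop("activation map and label volume are on different grids")
  dims <- dim(active)
  idx <- which(active)
  lab <- labels$labels[idx]
  excl <- lab %in% labels$excluded
  n_excluded <- sum(excl)
  idx <- idx[!excl]
  lab <- lab[!excl]
  if (any(lab == 0L))
    warning(sum(lab == 0L),
            " active voxel(s) on the background label kept as 'unlabeled' fROI(s)")
  nodes <- NULL
  for (id in sort(unique(lab))) {
    sub <- idx[lab == id]
    comp <- components_of_indices(sub, dims, connectivity)
    rn <- if (id == 0L) "unlabeled" else region_name(labels, id)
    nodes <- rbind(nodes, data.frame(
      index = sub, label_id = id, region = rn,
      froi = paste0(rn, "#", comp), unlabeled = id == 0L,
      stringsAsFactors = FALSE))
  }
  if (is.null(nodes))
    nodes <- data.frame(index = integer(), label_id = integer(),
                        region = character(), froi = character(),
                        unlabeled = logical())
  nodes <- nodes[order(nodes$index), , drop = FALSE]
  co <- arrayInd(nodes$index, dims)
  out <- data.frame(node = seq_len(nrow(nodes)), index = nodes$index,
                    x = co[, 1] - 1L, y = co[, 2] - 1L, z = co[, 3] - 1L,
                    label_id = nodes$label_id, region = nodes$region,
                    froi = nodes$froi, unlabeled = nodes$unlabeled,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  rownames(out) <- NULL
  out
}

#' Pairwise voxel BOLD correlations
#'
#' Pearson correlation between the time series of every pair of network
#' nodes. Constant series are flagged and their correlations set to 0.
#'
#' @param scan A [subject_scan()] (typically the `processed` scan of an
#'   activation map, so correlations see the same series as the
#'   statistics).
#' @param nodes Node table from [label_frois()] (needs >= 2 rows).
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `constant` flags degenerate series.
#' @export
voxel_correlations <- function(scan, nodes) {
  stopifnot(inherits(scan, "subject_scan"))
  if (nrow(nodes) < 2) stop("need at least 2 nodes")
  X <- t(scan_matrix(scan)[nodes$index, , drop = FALSE]) # time x nodes
  const <- apply(X, 2, stats::sd) == 0
  if (any(const))
    warning(sum(const), " constant node series; correlations set to 0")
  C <- suppressWarnings(stats::cor(X))
  C[is.na(C)] <- 0
  C[const, ] <- 0
  C[, const] <- 0
  diag(C) <- 1
  attr(C, "constant") <- const
  C
}

#' Binary voxel-scale network by correlation thresholding
#'
#' Links every pair of active voxels whose correlation magnitude reaches
#' theta: edge `(i, j)` present iff `|C_ij| >= theta`, `i != j`, with
#' binary weight 1. Both intra- and inter-fROI edges are kept; the
#' fraction of retained edges with negative correlation is reported.
#'
#' @param C Correlation matrix from [voxel_correlations()].
#' @param nodes Node table from [label_frois()].
#' @param theta Threshold in (0, 1].
#' @return An object of class `voxel_network`: `nodes`, `edges`
#'   (data.frame `i`, `j`, `C` with `i < j` as node ids), `theta`,
#'   `negative_fraction`.
#' @export
build_voxel_network <- function(C, nodes, theta) {
  if (!is.finite(theta) || theta <= 0 || theta > 1)
    stop("`theta` must be in (0, 1]")
  n <- nrow(nodes)
  stopifnot(nrow(C) == n, ncol(C) == n)
  keep <- abs(C) >= theta
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  wh <- which(keep, arr.ind = TRUE)
  edges <- data.frame(i = nodes$node[wh[, 1]], j = nodes$node[wh[, 2]],
                      C = C[wh])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, theta = theta,
                 negative_fraction = if (nrow(edges)) mean(edges$C < 0) else 0),
            class = "voxel_network")
}

#' @export
print.voxel_network <- function(x, ...) {
  cat(sprintf("<voxel_network> %d nodes, %d edges (theta = %g, %.1f%% negative)\n",
              nrow(x$nodes), nrow(x$edges), x$theta,
              100 * x$negative_fraction))
  invisible(x)
}

#' Aggregate a voxel network to the fROI scale
#'
#' fROI-scale link weight: the number of binarized voxel links between the
#' two fROIs, normalized by the sum of the two fROI sizes,
#' `W_ij = E_ij / (S_i + S_j)`. Intra-fROI edges contribute to no weight.
#'
#' @param net A [build_voxel_network()] result.
#' @param by `"froi"` (default) treats each connected component fROI as a
#'   node; `"region"` merges all fROIs with the same anatomical region name
#'   into one node (sizes and cross-links pooled), the resolution at which
#'   subjects are compared across a group.
#' @return An object of class `froi_network`: `nodes` (`froi`, `region`,
#'   `size`), `edges` (`froi_i`, `froi_j`, `region_i`, `region_j`,
#'   `n_cross`, `W`), `theta`.
#' @export
froi_weights <- function(net, by = c("froi", "region")) {
  by <- match.arg(by)
  stopifnot(inherits(net, "voxel_network"))
  nodes <- net$nodes
  key <- if (by == "froi") nodes$froi else nodes$region
  sizes <- table(key)
  nt <- data.frame(froi = names(sizes),
                   region = nodes$region[match(names(sizes), key)],
                   size = as.integer(sizes), stringsAsFactors = FALSE)
  nt <- nt[order(nt$froi), , drop = FALSE]
  rownames(nt) <- NULL
  e <- net$edges
  if (nrow(e)) {
    ki <- key[match(e$i, nodes$node)]
    kj <- key[match(e$j, nodes$node)]
    cross <- ki != kj
    a <- pmin(ki[cross], kj[cross])
    b <- pmax(ki[cross], kj[cross])
    if (length(a)) {
      cnt <- stats::aggregate(list(n_cross = rep(1L, length(a))),
                              by = list(froi_i = a, froi_j = b), FUN = sum)
      cnt$region_i <- nt$region[match(cnt$froi_i, nt$froi)]
      cnt$region_j <- nt$region[match(cnt$froi_j, nt$froi)]
      Si <- nt$size[match(cnt$froi_i, nt$froi)]
      Sj <- nt$size[match(cnt$froi_j, nt$froi)]
      cnt$W <- cnt$n_cross / (Si + Sj)
      edges <- cnt[order(cnt$froi_i, cnt$froi_j),
                   c("froi_i", "froi_j", "region_i", "region_j", "n_cross", "W")]
      rownames(edges) <- NULL
    } else edges <- NULL
  } else edges <- NULL
  if (is.null(edges))
    edges <- data.frame(froi_i = character(), froi_j = character(),
                        region_i = character(), region_j = character(),
                        n_cross = integer(), W = numeric(),
                        stringsAsFactors = FALSE)
  structure(list(nodes = nt, edges = edges, theta = net$theta, by = by),
            class = "froi_network")
}

#' @export
print.froi_network <- function(x, ...) {
  cat(sprintf("<froi_network by %s> %d nodes, %d weighted links\n",
              x$by, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Subject-level network construction, end to end
#'
#' Convenience wrapper running activation mapping, fROI labeling, voxel
#' correlations and both network scales for one subject.
#'
#' @param scan A [subject_scan()].
#' @param labels A [label_map()].
#' @param cfg An [analysis_config()].
#' @param amap Optional precomputed [cluster_threshold()] map.
#' @return List with `amap`, `nodes`, `voxel_net`, `froi_net` (per
#'   component) and `region_net` (per anatomical region).
#' @export
subject_network <- function(scan, labels, cfg = analysis_config(),
                            amap = NULL) {
  if (is.null(amap)) amap <- cluster_threshold(scan, cfg)
  nodes <- label_frois(amap, labels, cfg$connectivity)
  if (nrow(nodes) < 2) {
    return(list(amap = amap, nodes = nodes, voxel_net = NULL,
                froi_net = NULL, region_net = NULL))
  }
  C <- voxel_correlations(amap$processed, nodes)
  vnet <- build_voxel_network(C, nodes, cfg$corr_threshold)
  list(amap = amap, nodes = nodes, voxel_net = vnet,
       froi_net = froi_weights(vnet, by = "froi"),
       region_net = froi_weights(vnet, by = "region"))
}
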