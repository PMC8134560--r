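# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (definition-level loops) so they can arbitrate the
# package's implementations.

# k-core membership by exhaustive iterative deletion, straight from the
# definition: for each k, repeatedly drop nodes of degree < k; a node's
# shell is the largest k whose k-core still contains it.
oracle_kshell <- function(n, edges) {
  in_core <- function(k) {
    alive <- rep(TRUE, n)
    repeat {
      deg <- rep(0L, n)
      if (nrow(edges)) {
        keep <- alive[edges$i] & alive[edges$j]
        for (e in which(keep)) {
          deg[edges$i[e]] <- deg[edges$i[e]] + 1L
          deg[edges$j[e]] <- deg[edges$j[e]] + 1L
        }
      }
      drop <- alive & deg < k
      if (!any(drop)) return(alive)
      alive[drop] <- FALSE
    }
  }
  shell <- rep(0L, n)
  k <- 1L
  repeat {
    core <- in_core(k)
    if (!any(core)) break
    shell[core] <- k
    k <- k + 1L
  }
  shell
}

# Erdos-Renyi edge list on n nodes
random_graph <- function(n, p) {
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(i = pairs[keep, 1], j = pairs[keep, 2])
}

# voxel_network from a bare graph: nodes carry region labels so fROI and
# k-shell machinery can run on constructed cases
vnet_from_graph <- function(n, edges, region = rep("R1", n)) {
  nodes <- data.frame(node = seq_len(n), index = seq_len(n),
                      x = seq_len(n) - 1L, y = 0L, z = 0L,
                      label_id = as.integer(factor(region)),
                      region = region,
                      froi = paste0(region, "#1"),
                      unlabeled = FALSE, stringsAsFactors = FALSE)
  edges <- if (nrow(edges))
    data.frame(i = as.integer(pmin(edges$i, edges$j)),
               j = as.integer(pmax(edges$i, edges$j)), C = 1)
  else data.frame(i = integer(), j = integer(), C = numeric())
  structure(list(nodes = nodes, edges = edges, theta = 0.5,
                 negative_fraction = 0),
            class = "voxel_network")
}

# Eq.-2 weights by definition: double loop over every cross voxel pair
oracle_froi_weights <- function(net) {
  nodes <- net$nodes
  adj <- matrix(FALSE, nrow(nodes), nrow(nodes))
  if (nrow(net$edges))
    for (e in seq_len(nrow(net$edges)))
      adj[net$edges$i[e], net$edges$j[e]] <-
        adj[net$edges$j[e], net$edges$i[e]] <- TRUE
  regs <- sort(unique(nodes$region))
  out <- list()
  for (a in seq_along(regs)) for (b in seq_along(regs)) {
    if (a >= b) next
    ia <- which(nodes$region == regs[a])
    ib <- which(nodes$region == regs[b])
    cnt <- 0L
    for (l in ia) for (m in ib) if (adj[l, m]) cnt <- cnt + 1L
    if (cnt > 0)
      out[[length(out) + 1L]] <- data.frame(
        region_i = regs[a], region_j = regs[b], n_cross = cnt,
        W = cnt / (length(ia) + length(ib)), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(region_i = character(),
                                      region_j = character(),
                                      n_cross = integer(), W = numeric()))
  do.call(rbind, out)
}

# froi_network built directly from a link list, for the group-level
# machinery (weights optional; sizes default 10)
fnet_from_links <- function(links, regions = NULL, sizes = NULL) {
  if (is.null(regions))
    regions <- sort(unique(c(links$region_i, links$region_j)))
  if (is.null(sizes)) sizes <- rep(10L, length(regions))
  nodes <- data.frame(froi = regions, region = regions,
                      size = as.integer(sizes), stringsAsFactors = FALSE)
  if (is.null(links$W)) links$W <- 1
  if (is.null(links$n_cross)) links$n_cross <- 1L
  edges <- data.frame(froi_i = links$region_i, froi_j = links$region_j,
                      region_i = links$region_i, region_j = links$region_j,
                      n_cross = links$n_cross, W = links$W,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, theta = 0.6, by = "region"),
            class = "froi_network")
}

# small two-region synthetic configuration for fast end-to-end runs
mini_config <- function(noise_sd = 1, couple = 0.9, beta = 4,
                        jitter = 0.1, seed = 1L) {
  regions <- list(
    region_spec("Alpha", 1L, origin = c(3, 3, 2), size = c(3, 3, 2),
                beta = beta, within_coupling = 1),
    region_spec("Beta",  2L, origin = c(9, 8, 3), size = c(3, 3, 2),
                beta = beta, within_coupling = 1),
    region_spec("Vis",   3L, origin = c(10, 2, 5), size = c(2, 2, 2),
                beta = beta, within_coupling = 1, excluded = TRUE))
  cp <- c(couple)
  names(cp) <- canonical_pair("Alpha", "Beta")
  synthetic_config(grid_shape = c(14, 12, 7), voxel_size_mm = 4,
                   paradigm = task_paradigm(4, 20, 30, 2.5),
                   regions = regions, between_coupling = cp,
                   noise_sd = noise_sd, baseline = 100,
                   subject_jitter_sd = jitter, seed = seed)
}

# pure-noise configuration (uniform-p null) on an arbitrary grid
null_config <- function(grid = c(10, 10, 5), n_epochs = 8) {
  synthetic_config(grid_shape = grid, voxel_size_mm = 4,
                   paradigm = task_paradigm(n_epochs, 20, 30, 2.5),
                   regions = list(), between_coupling = numeric(),
                   noise_sd = 1, baseline = 100, subject_jitter_sd = 0)
}
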