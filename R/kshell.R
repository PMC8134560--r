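#' k-shell decomposition of a binary network
#'
#' Standard iterative pruning on the unweighted graph: nodes removed while
#' peeling at degree threshold k belong to shell k, so a node in shell k is
#' in the k-core but not the (k + 1)-core. Isolated nodes get shell 0. The
#' decomposition runs on the whole (possibly disconnected) graph; the
#' maximum shell index is the subject's `k_max` and its nodes form the
#' maximum core.
#'
#' @param net A [build_voxel_network()] result, or a list with `n_nodes`
#'   and an integer `edges` data.frame (`i`, `j`, node ids 1..n).
#' @return Object of class `shell_assignment`: `shell` (integer per node),
#'   `k_max`, `nodes` (node table when available, with `region` module
#'   labels).
#' @export
kshell_decomposition <- function(net) {
  if (inherits(net, "voxel_network")) {
    n <- nrow(net$nodes)
    edges <- net$edges[, c("i", "j")]
    nodes <- net$nodes
  } else {
    n <- net$n_nodes
    edges <- as.data.frame(net$edges)[, c("i", "j")]
    nodes <- net$nodes
  }
  if (is.null(n) || n < 1) stop("network has no nodes")
  if (nrow(edges) && (any(edges$i == edges$j)))
    stop("self-loops are not allowed")
  adj <- vector("list", n)
  if (nrow(edges)) {
    tgt <- split(c(edges$j, edges$i), c(edges$i, edges$j))
    adj[as.integer(names(tgt))] <- tgt
  }
  deg <- lengths(adj)
  shell <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0L
  n_left <- n
  while (n_left > 0) {
    q <- which(alive & deg <= k)
    if (!length(q)) {
      k <- max(k + 1L, min(deg[alive]))
      next
    }
    while (length(q)) {
      v <- q[[1]]
      q <- q[-1]
      if (!alive[v]) next
      alive[v] <- FALSE
      shell[v] <- k
      n_left <- n_left - 1L
      for (u in adj[[v]]) {
        if (alive[u]) {
          deg[u] <- deg[u] - 1L
          if (deg[u] <= k) q <- c(q, u)
        }
      }
    }
  }
  structure(list(shell = shell, k_max = max(shell), nodes = nodes),
            class = "shell_assignment")
}

#' @export
print.shell_assignment <- function(x, ...) {
  cat(sprintf("<shell_assignment> %d nodes, k_max = %d\n",
              length(x$shell), x$k_max))
  invisible(x)
}

#' Normalize shell indices by the subject's maximum shell
#'
#' Maps each node to `k_s / k_max` in (0, 1]; shell-0 (isolated) nodes map
#' to 0 and are flagged. An edgeless network (`k_max = 0`) is an error.
#'
#' @param assign A [kshell_decomposition()] result.
#' @param subject Optional subject label used in error messages.
#' @return Numeric vector of normalized shells with attribute `isolated`
#'   (logical).
#' @export
normalize_shells <- function(assign, subject = NULL) {
  stopifnot(inherits(assign, "shell_assignment"))
  if (assign$k_max < 1)
    stop("k_max = 0 (edgeless network)",
         if (!is.null(subject)) paste0(" for subject '", subject, "'") else "")
  out <- assign$shell / assign$k_max
  attr(out, "isolated") <- assign$shell == 0L
  out
}

#' Pooled normalized shell-occupancy histograms per module
#'
#' Pools the nodes of all subjects in a group (regardless of subject),
#' splits them by module (anatomical region), and bins their normalized
#' shell values into `n_bins` bins over (0, 1]: bin b covers
#' `[(b-1)/n_bins, b/n_bins)` with the last bin closed at 1. Masses are
#' normalized to sum to 1 per (module, group); isolated (shell 0) nodes
#' fall into bin 1 and their count is reported.
#'
#' @param assignments List of per-subject [kshell_decomposition()] results
#'   whose `nodes` tables carry a `region` column.
#' @param group Group name.
#' @param n_bins Number of bins (default 15).
#' @param modules Optional character vector restricting/ordering the
#'   modules; default: all regions observed (excluding "unlabeled").
#' @return Object of class `occupancy_histogram`: `group`, `n_bins`,
#'   `breaks`, and `modules`, a named list with `mass`, `counts`, `n`,
#'   `n_isolated` per module. Modules with an empty pool are reported as
#'   missing (`NULL` mass), not as zeros.
#' @export
occupancy_histogram <- function(assignments, group = "group", n_bins = 15,
                                modules = NULL) {
  if (!length(assignments)) stop("no shell assignments")
  if (!is.finite(n_bins) || n_bins < 1) stop("`n_bins` must be >= 1")
  n_bins <- as.integer(n_bins)
  ks <- reg <- NULL
  for (s in seq_along(assignments)) {
    a <- assignments[[s]]
    stopifnot(inherits(a, "shell_assignment"))
    if (is.null(a$nodes) || is.null(a$nodes$region))
      stop("assignment ", s, " carries no region module labels")
    ks <- c(ks, normalize_shells(a, subject = s))
    reg <- c(reg, a$nodes$region)
  }
  if (is.null(modules)) modules <- sort(unique(reg[reg != "unlabeled"]))
  out <- vector("list", length(modules))
  names(out) <- modules
  for (m in modules) {
    v <- ks[reg == m]
    if (!length(v)) { out[m] <- list(NULL); next }
    b <- pmin(floor(v * n_bins) + 1L, n_bins)  # v = 1 lands in the last bin
    counts <- tabulate(b, nbins = n_bins)
    out[[m]] <- list(mass = counts / sum(counts), counts = counts,
                     n = length(v), n_isolated = sum(v == 0))
  }
  structure(list(group = group, n_bins = n_bins,
                 breaks = seq(0, 1, length.out = n_bins + 1), modules = out),
            class = "occupancy_histogram")
}

#' @export
print.occupancy_histogram <- function(x, ...) {
  cat(sprintf("<occupancy_histogram '%s'> %d bins; modules: %s\n", x$group,
              x$n_bins, paste(names(x$modules), collapse = ", ")))
  invisible(x)
}

#' Sum of squared errors between group occupancy histograms
#'
#' For each module and each unordered pair of groups, the sum over bins of
#' the squared difference of occupancy masses. Pairs with a missing
#' histogram are skipped with a message.
#'
#' @param hists List of [occupancy_histogram()] objects (one per group,
#'   same `n_bins`).
#' @return data.frame `module`, `group1`, `group2`, `sse`.
#' @export
sse_between_groups <- function(hists) {
  if (length(hists) < 2) stop("need at least two group histograms")
  nb <- unique(vapply(hists, function(h) as.numeric(h$n_bins), numeric(1)))
  if (length(nb) != 1) stop("histograms disagree on the number of bins")
  groups <- vapply(hists, `[[`, "", "group")
  if (anyDuplicated(groups)) stop("duplicate group names")
  modules <- unique(unlist(lapply(hists, function(h) names(h$modules))))
  rows <- list()
  for (m in modules) {
    for (i in seq_along(hists)) for (j in seq_along(hists)) {
      if (i >= j) next
      h1 <- hists[[i]]$modules[[m]]
      h2 <- hists[[j]]$modules[[m]]
      if (is.null(h1) || is.null(h2)) {
        message("module '", m, "': missing histogram for pair ",
                groups[i], " vs ", groups[j], "; skipped")
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(module = m, group1 = groups[i], group2 = groups[j],
                   sse = sum((h1$mass - h2$mass)^2), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(module = character(), group1 = character(),
                      group2 = character(), sse = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bar plot of shell-occupancy histograms
#'
#' Base-graphics rendering of per-module occupancy; one panel per module,
#' grouped bars per group.
#'
#' @param hists List of [occupancy_histogram()] objects.
#' @param modules Modules to plot (default: union over groups).
#' @return Invisibly `NULL`; draws on the current device.
#' @export
plot_occupancy <- function(hists, modules = NULL) {
  if (inherits(hists, "occupancy_histogram")) hists <- list(hists)
  if (is.null(modules))
    modules <- unique(unlist(lapply(hists, function(h) names(h$modules))))
  old <- graphics::par(mfrow = c(length(modules), 1),
                       mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(old))
  nb <- hists[[1]]$n_bins
  mids <- (seq_len(nb) - 0.5) / nb
  for (m in modules) {
    mm <- t(vapply(hists, function(h) {
      x <- h$modules[[m]]
      if (is.null(x)) rep(NA_real_, nb) else x$mass
    }, numeric(nb)))
    graphics::barplot(mm, beside = TRUE, names.arg = round(mids, 2),
                      main = m, ylab = "occupancy",
                      legend.text = vapply(hists, `[[`, "", "group"),
                      args.legend = list(x = "topleft", bty = "n", cex = 0.8))
  }
  invisible(NULL)
}
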