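#' Link appearance counts across subjects
#'
#' Counts, for every region pair, the number of subject networks in which
#' the pair is connected with positive weight.
#'
#' @param nets List of region-level [froi_weights()] networks (one per
#'   subject; `by = "region"` resolution so naming is consistent).
#' @return data.frame `region_i`, `region_j`, `count` (pairs never present
#'   are absent).
#' @export
link_frequency <- function(nets) {
  if (!length(nets)) stop("empty network list")
  acc <- list()
  for (net in nets) {
    stopifnot(inherits(net, "froi_network"))
    e <- net$edges
    e <- e[e$W > 0, , drop = FALSE]
    if (!nrow(e)) next
    a <- pmin(e$region_i, e$region_j)
    b <- pmax(e$region_i, e$region_j)
    for (k in seq_along(a)) {
      key <- paste(a[k], b[k], sep = "|")
      acc[[key]] <- (if (is.null(acc[[key]])) 0L else acc[[key]]) + 1L
    }
  }
  if (!length(acc))
    return(data.frame(region_i = character(), region_j = character(),
                      count = integer(), stringsAsFactors = FALSE))
  pr <- do.call(rbind, strsplit(names(acc), "|", fixed = TRUE))
  out <- data.frame(region_i = pr[, 1], region_j = pr[, 2],
                    count = unlist(acc, use.names = FALSE),
                    stringsAsFactors = FALSE)
  out <- out[order(out$region_i, out$region_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group-level common network
#'
#' Retains the region pairs whose link appears in at least
#' `ceiling(tau * N)` of the `N` subject networks and averages the link
#' weight over the subjects where the link is present (with the default
#' `tau = 1` this is the plain mean over all subjects, since the link must
#' be present everywhere). Node sizes are averaged over the subjects in
#' which the region appears.
#'
#' @param nets List of region-level [froi_weights()] networks.
#' @param tau Retention fraction in (0, 1]; default 1 (all subjects).
#' @param group Group name.
#' @return Object of class `common_network`: `group`, `N`, `nodes`
#'   (`region`, `mean_size`, `n_present`), `edges` (`region_i`,
#'   `region_j`, `W_common`, `f` appearance count, `retained`). All
#'   observed links are listed; `retained` marks those meeting the
#'   frequency rule.
#' @export
build_common_network <- function(nets, tau = 1, group = "group") {
  if (!length(nets)) stop("empty network list")
  if (!is.finite(tau) || tau <= 0 || tau > 1) stop("`tau` must be in (0, 1]")
  N <- length(nets)
  freq <- link_frequency(nets)
  wsum <- numeric(nrow(freq))
  key <- paste(freq$region_i, freq$region_j, sep = "|")
  node_size <- list()
  for (net in nets) {
    e <- net$edges[net$edges$W > 0, , drop = FALSE]
    if (nrow(e)) {
      k <- paste(pmin(e$region_i, e$region_j), pmax(e$region_i, e$region_j),
                 sep = "|")
      m <- match(k, key)
      wsum[m] <- wsum[m] + e$W
    }
    for (r in seq_len(nrow(net$nodes)))
      node_size[[net$nodes$region[r]]] <-
        c(node_size[[net$nodes$region[r]]], net$nodes$size[r])
  }
  edges <- data.frame(region_i = freq$region_i, region_j = freq$region_j,
                      W_common = ifelse(freq$count > 0, wsum / freq$count, 0),
                      f = freq$count,
                      retained = freq$count >= ceiling(tau * N),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(region = names(node_size),
                      mean_size = vapply(node_size, mean, numeric(1)),
                      n_present = lengths(node_size),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$region), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(group = group, N = N, nodes = nodes, edges = edges,
                 tau = tau),
            class = "common_network")
}

#' @export
print.common_network <- function(x, ...) {
  cat(sprintf("<common_network '%s'> N = %d, %d regions, %d/%d links retained (tau = %g)\n",
              x$group, x$N, nrow(x$nodes), sum(x$edges$retained),
              nrow(x$edges), x$tau))
  invisible(x)
}

#' Default role mapping for the language-network structures
#'
#' Maps the four structural roles (preSMA, BA, preMA, WA) to the region
#' names used by [language_cohort_config()].
#' @return Named character vector.
#' @export
default_roles <- function() {
  c(preSMA = "pre-SMA", BA = "BA(L)", preMA = "v-preMA(L)", WA = "WA(L)")
}

#' Detect triangle and V structures
#'
#' The triangle structure is the fully connected trio preSMA--BA--preMA;
#' the V structure is the pair of links WA--BA and WA--preMA. A structure
#' involving a role whose region is missing from a subject's network is
#' absent in that subject.
#'
#' @param nets List of region-level [froi_weights()] networks.
#' @param roles Named character vector mapping roles `preSMA`, `BA`,
#'   `preMA`, `WA` to region names (default [default_roles()]).
#' @param group Group name.
#' @return Object of class `structure_report`: `per_subject` data.frame
#'   (`subject`, `triangle`, `v`), counts and fractions per structure.
#' @export
detect_structures <- function(nets, roles = default_roles(), group = "group") {
  if (!length(nets)) stop("empty network list")
  need <- c("preSMA", "BA", "preMA", "WA")
  if (!all(need %in% names(roles)))
    stop("`roles` must name all of: ", paste(need, collapse = ", "))
  has_link <- function(net, a, b) {
    e <- net$edges
    any(((e$region_i == a & e$region_j == b) |
           (e$region_i == b & e$region_j == a)) & e$W > 0)
  }
  tri <- v <- logical(length(nets))
  for (k in seq_along(nets)) {
    net <- nets[[k]]
    tri[k] <- has_link(net, roles["preSMA"], roles["BA"]) &&
      has_link(net, roles["preSMA"], roles["preMA"]) &&
      has_link(net, roles["BA"], roles["preMA"])
    v[k] <- has_link(net, roles["WA"], roles["BA"]) &&
      has_link(net, roles["WA"], roles["preMA"])
  }
  N <- length(nets)
  structure(list(
    group = group, N = N,
    per_subject = data.frame(subject = seq_len(N), triangle = tri, v = v),
    triangle_count = sum(tri), triangle_fraction = mean(tri),
    v_count = sum(v), v_fraction = mean(v), roles = roles),
    class = "structure_report")
}

#' @export
print.structure_report <- function(x, ...) {
  cat(sprintf("<structure_report '%s'> triangle %d/%d (%.0f%%), V %d/%d (%.0f%%)\n",
              x$group, x$triangle_count, x$N, 100 * x$triangle_fraction,
              x$v_count, x$N, 100 * x$v_fraction))
  invisible(x)
}

#' Named core links A..E
#'
#' The five named links of the language core, in the conventional order:
#' A = BA--preMA, B = preSMA--preMA, C = preSMA--BA, D = BA--WA,
#' E = preMA--WA.
#'
#' @param roles Role mapping as in [detect_structures()].
#' @return data.frame `link`, `region_i`, `region_j`.
#' @export
named_links <- function(roles = default_roles()) {
  data.frame(
    link = c("A", "B", "C", "D", "E"),
    region_i = unname(roles[c("BA", "preSMA", "preSMA", "BA", "preMA")]),
    region_j = unname(roles[c("preMA", "preMA", "BA", "WA", "WA")]),
    stringsAsFactors = FALSE)
}

#' Rank the named core links by common-network weight
#'
#' Sorts the named links by `W_common` descending. Links absent from the
#' common network are placed last and flagged; exact ties share a tie
#' group and are flagged, never ordered silently.
#'
#' @param common A [build_common_network()] result.
#' @param links Named link table (default [named_links()]).
#' @param retained_only If `TRUE` (default) only links meeting the
#'   retention rule count as present.
#' @return data.frame `link`, `region_i`, `region_j`, `W_common`, `f`,
#'   `present`, `tie`, sorted by descending weight with absents last.
#' @export
rank_links <- function(common, links = named_links(), retained_only = TRUE) {
  stopifnot(inherits(common, "common_network"))
  e <- common$edges
  if (retained_only) e <- e[e$retained, , drop = FALSE]
  W <- f <- rep(NA_real_, nrow(links))
  for (k in seq_len(nrow(links))) {
    hit <- (e$region_i == links$region_i[k] & e$region_j == links$region_j[k]) |
      (e$region_i == links$region_j[k] & e$region_j == links$region_i[k])
    if (any(hit)) {
      W[k] <- e$W_common[which(hit)[1]]
      f[k] <- e$f[which(hit)[1]]
    }
  }
  out <- data.frame(links, W_common = W, f = f, present = !is.na(W),
                    stringsAsFactors = FALSE)
  out <- out[order(!out$present, -ifelse(is.na(out$W_common), -Inf,
                                         out$W_common), out$link), ,
             drop = FALSE]
  out$tie <- out$present &
    (duplicated(out$W_common) | duplicated(out$W_common, fromLast = TRUE))
  rownames(out) <- NULL
  out
}
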