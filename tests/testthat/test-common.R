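test_that("link frequency counts subjects with a positive link", {
  nets <- c(
    replicate(6, fnet_from_links(data.frame(region_i = "A", region_j = "B",
                                            W = 0.5)), simplify = FALSE),
    replicate(2, fnet_from_links(data.frame(region_i = "A", region_j = "C",
                                            W = 0.2)), simplify = FALSE))
  freq <- link_frequency(nets)
  expect_equal(freq$count[freq$region_i == "A" & freq$region_j == "B"], 6L)
  expect_equal(freq$count[freq$region_j == "C"], 2L)
  # absent pairs do not appear
  expect_false(any(freq$region_i == "B" & freq$region_j == "C"))
  expect_error(link_frequency(list()), "empty")
})

test_that("common network averages over present subjects and applies retention", {
  n1 <- fnet_from_links(data.frame(region_i = "A", region_j = "B", W = 0.4))
  n2 <- fnet_from_links(data.frame(region_i = "A", region_j = "B", W = 0.6))
  cn <- build_common_network(list(n1, n2), tau = 1)
  expect_equal(cn$edges$W_common, 0.5)
  expect_true(cn$edges$retained)
  expect_equal(cn$edges$f, 2L)

  # link in 2 of 3 subjects is dropped at tau = 1 ...
  n3 <- fnet_from_links(data.frame(region_i = "A", region_j = "C", W = 0.1))
  cn3 <- build_common_network(list(n1, n2, n3), tau = 1)
  ab <- cn3$edges[cn3$edges$region_j == "B", ]
  expect_false(ab$retained)
  # ... but kept at tau = 0.6 with the present-subject mean 0.45
  w13 <- fnet_from_links(data.frame(region_i = "A", region_j = "B", W = 0.3))
  w23 <- fnet_from_links(data.frame(region_i = "A", region_j = "B", W = 0.6))
  other <- fnet_from_links(data.frame(region_i = "A", region_j = "C", W = 1))
  cn06 <- build_common_network(list(w13, w23, other), tau = 0.6)
  ab06 <- cn06$edges[cn06$edges$region_j == "B", ]
  expect_true(ab06$retained)
  expect_equal(ab06$W_common, 0.45)

  expect_error(build_common_network(list(n1), tau = 0), "tau")
  expect_error(build_common_network(list(n1), tau = 1.2), "tau")
})

test_that("with tau = 1 every retained link appears in all subjects", {
  set.seed(20)
  nets <- lapply(1:8, function(s) {
    pairs <- data.frame(region_i = c("A", "A", "B"),
                        region_j = c("B", "C", "C"),
                        W = runif(3))
    fnet_from_links(pairs[runif(3) < 0.8, , drop = FALSE])
  })
  cn <- build_common_network(nets, tau = 1)
  expect_true(all(cn$edges$f[cn$edges$retained] == 8L))
})

test_that("common weights ignore subject ordering and list duplication", {
  set.seed(21)
  nets <- lapply(1:5, function(s)
    fnet_from_links(data.frame(region_i = "A", region_j = "B",
                               W = runif(1))))
  w1 <- build_common_network(nets, tau = 1)$edges$W_common
  w2 <- build_common_network(rev(nets), tau = 1)$edges$W_common
  w3 <- build_common_network(c(nets, nets), tau = 1)$edges$W_common
  expect_equal(w1, w2)
  expect_equal(w1, w3)
})

test_that("triangle and V structures are detected from the role links", {
  roles <- default_roles()
  tri_links <- data.frame(
    region_i = c("pre-SMA", "pre-SMA", "BA(L)"),
    region_j = c("BA(L)", "v-preMA(L)", "v-preMA(L)"), W = 1)
  v_links <- data.frame(region_i = c("WA(L)", "WA(L)"),
                        region_j = c("BA(L)", "v-preMA(L)"), W = 1)
  full <- fnet_from_links(rbind(tri_links, v_links))
  tri_only <- fnet_from_links(tri_links)
  half_v <- fnet_from_links(rbind(tri_links, v_links[1, ]))
  rep1 <- detect_structures(list(full, tri_only, half_v), roles)
  expect_equal(rep1$per_subject$triangle, c(TRUE, TRUE, TRUE))
  expect_equal(rep1$per_subject$v, c(TRUE, FALSE, FALSE))
  expect_equal(rep1$triangle_fraction, 1)
  expect_equal(rep1$v_count, 1L)
})

test_that("planting V links in 6 of 8 subjects reports exactly 6/8", {
  roles <- default_roles()
  tri <- data.frame(region_i = c("pre-SMA", "pre-SMA", "BA(L)"),
                    region_j = c("BA(L)", "v-preMA(L)", "v-preMA(L)"), W = 1)
  v <- data.frame(region_i = c("WA(L)", "WA(L)"),
                  region_j = c("BA(L)", "v-preMA(L)"), W = 1)
  nets <- lapply(1:8, function(s)
    if (s <= 6) fnet_from_links(rbind(tri, v)) else fnet_from_links(tri))
  rep6 <- detect_structures(nets, roles)
  expect_equal(rep6$v_count, 6L)
  expect_equal(rep6$v_fraction, 6 / 8)
  expect_equal(rep6$triangle_count, 8L)

  none <- detect_structures(lapply(1:8, function(s) fnet_from_links(tri)),
                            roles)
  expect_equal(none$v_count, 0L)
})

test_that("link ranking sorts by weight, flags missing links and ties", {
  roles <- default_roles()
  nl <- named_links(roles)
  links <- data.frame(
    region_i = nl$region_i, region_j = nl$region_j,
    W = c(0.5, 0.4, 0.3, 0.2, 0.1))
  cn <- build_common_network(list(fnet_from_links(links)), tau = 1)
  rk <- rank_links(cn, nl)
  expect_equal(rk$link, c("A", "B", "C", "D", "E"))
  expect_false(any(rk$tie))

  # D missing: flagged and placed last
  cn2 <- build_common_network(list(fnet_from_links(links[-4, ])), tau = 1)
  rk2 <- rank_links(cn2, nl)
  expect_equal(rk2$link, c("A", "B", "C", "E", "D"))
  expect_false(rk2$present[5])

  # exact tie between B and C is flagged, not silently ordered
  links3 <- links
  links3$W <- c(0.5, 0.4, 0.4, 0.2, 0.1)
  rk3 <- rank_links(build_common_network(list(fnet_from_links(links3)),
                                         tau = 1), nl)
  expect_setequal(rk3$link[rk3$tie], c("B", "C"))
})
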