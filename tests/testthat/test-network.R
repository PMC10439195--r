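test_that("perfectly correlated pair gives a single positive edge", {
  set.seed(1)
  x <- rnorm(100)
  net <- infer_network(rbind(U = x, V = 2 * x + 1))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$sign, "+")
  expect_equal(net$edges$weight, 1, tolerance = 1e-9)
})

test_that("conditioning on the middle of a Gaussian chain removes the X-Z edge", {
  set.seed(1)
  n <- 500
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n, 0, sqrt(1 - 0.64))
  z <- 0.8 * y + rnorm(n, 0, sqrt(1 - 0.64))
  net <- infer_network(rbind(X = x, Y = y, Z = z))
  key <- paste(net$edges$from, net$edges$to)
  expect_setequal(key, c("X Y", "Y Z"))
  expect_true(all(net$edges$cond_set_size == 1))
})

test_that("heterogeneous mode strips habitat-driven edges via meta variables", {
  set.seed(2)
  meta <- rep(c(0, 1), each = 250)
  m <- rbind(A = 1.5 * meta + rnorm(500), B = 1.5 * meta + rnorm(500))
  expect_equal(nrow(infer_network(m)$edges), 1)
  expect_equal(nrow(infer_network(m, meta_variables = factor(meta))$edges), 0)
})

test_that("inference is invariant to taxa permutation", {
  sim <- generate_community(synthetic_design(n_stations = 12,
                                             n_omz_stations = 6,
                                             taxa_per_group = c(prokaryote = 30),
                                             n_modules = 2, module_taxa = 8,
                                             module_strength = 2, seed = 9))
  cl <- robust_clr(sim$otu)
  net1 <- infer_network(cl, max_k = 1)
  perm <- rev(seq_len(nrow(cl$values)))
  cl2 <- cl; cl2$values <- cl$values[perm, ]; cl2$mask <- cl$mask[perm, ]
  net2 <- infer_network(cl2, max_k = 1)
  canon <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  expect_setequal(canon(net1$edges), canon(net2$edges))
})

test_that("null data yields close to the nominal false-discovery budget", {
  set.seed(44)
  m <- matrix(rnorm(100 * 50), 50, 100,
              dimnames = list(paste0("t", 1:50), paste0("s", 1:100)))
  net <- infer_network(m, alpha = 0.01)
  pairs <- choose(50, 2)
  expect_lte(nrow(net$edges), 0.01 * pairs * 3)
})

test_that("constant taxa are excluded with a warning", {
  set.seed(3)
  m <- rbind(A = rnorm(30), B = rnorm(30), C = rep(1, 30))
  expect_warning(net <- infer_network(m), "Constant")
  expect_false("C" %in% net$nodes$taxon_id)
})

test_that("greedy modularity matches exhaustive search on small graphs", {
  fixtures <- list(
    bridge = bridge_graph(),
    k3k3 = make_net(c("a", "a", "b", "d", "d", "e"),
                    c("b", "c", "c", "e", "f", "f")),
    k4 = make_net(c("a", "a", "a", "b", "b", "c"),
                  c("b", "c", "d", "c", "d", "d")),
    path4 = make_net(c("a", "b", "c"), c("b", "c", "d")),
    star5 = make_net(rep("hub", 4), c("a", "b", "c", "d")),
    two_squares = make_net(c("a", "b", "c", "d", "d", "e", "f", "g", "h"),
                           c("b", "c", "d", "a", "e", "f", "g", "h", "e")))
  for (nm in names(fixtures)) {
    net <- fixtures[[nm]]
    part <- cnm_modules(net)
    expect_equal(part$Q, brute_force_best_q(net), tolerance = 1e-9,
                 label = paste("Q on", nm))
    # reported Q is consistent with the first-principles formula
    memb <- part$membership$module[match(net$nodes$taxon_id,
                                         part$membership$taxon_id)]
    expect_equal(part$Q, modularity_by_hand(net, memb), tolerance = 1e-9)
  }
})

test_that("two-triangle bridge partitions into its triangles with Q = 0.3571", {
  part <- cnm_modules(bridge_graph())
  expect_equal(part$Q, 2 * (3 / 7 - 0.25), tolerance = 1e-9)
  memb <- part$membership
  expect_equal(length(unique(memb$module)), 2)
  expect_equal(length(unique(memb$module[memb$taxon_id %in% c("a", "b", "c")])), 1)
  expect_equal(length(unique(memb$module[memb$taxon_id %in% c("d", "e", "f")])), 1)

  # single clique collapses to one module at Q = 0
  k3 <- make_net(c("a", "a", "b"), c("b", "c", "c"))
  p3 <- cnm_modules(k3)
  expect_equal(p3$Q, 0, tolerance = 1e-12)
  expect_equal(length(unique(p3$membership$module)), 1)

  # disconnected cliques: two modules, Q = 0.5
  k3k3 <- make_net(c("a", "a", "b", "d", "d", "e"),
                   c("b", "c", "c", "e", "f", "f"))
  expect_equal(cnm_modules(k3k3)$Q, 0.5, tolerance = 1e-12)
})

test_that("greedy modularity agrees with the igraph reference on random graphs", {
  set.seed(12)
  for (i in 1:3) {
    g <- igraph::sample_gnp(25, 0.12)
    while (igraph::ecount(g) < 5) g <- igraph::sample_gnp(25, 0.12)
    igraph::V(g)$name <- paste0("n", 1:25)
    part <- cnm_modules(g)
    # reported Q must equal the igraph modularity of the same membership
    memb <- part$membership$module[match(igraph::V(g)$name,
                                         part$membership$taxon_id)]
    expect_equal(part$Q, igraph::modularity(g, memb), tolerance = 1e-9)
    # and sit close to the independent greedy reference (tie-breaking and
    # merge order legitimately differ between greedy variants)
    ref <- igraph::cluster_fast_greedy(g)
    expect_lt(abs(part$Q - igraph::modularity(ref)), 0.1)
  }
})

test_that("module enrichment reproduces the hypergeometric tail", {
  net <- make_net(c("a", "b", "c", "d", "e", "f", "g"),
                  c("b", "c", "d", "a", "f", "g", "h"))
  part <- list(membership = tibble::tibble(taxon_id = letters[1:8],
                                           module = rep(1:2, each = 4)),
               summaries = tibble::tibble(module = 1:2, size = c(4L, 4L)))
  calls <- tibble::tibble(taxon_id = letters[1:8],
                          call = rep(c("OMZ", "EPI"), each = 4))
  enr <- module_enrichment(net, part, calls)
  expect_equal(enr$p[enr$module == 1 & enr$class == "OMZ"], 1 / 70,
               tolerance = 1e-12)
  # cross-check against the closed-form hypergeometric tail
  expect_equal(enr$p[enr$module == 1 & enr$class == "OMZ"],
               phyper(3, 4, 4, 4, lower.tail = FALSE), tolerance = 1e-12)

  # module spanning the whole network cannot be enriched
  whole <- list(membership = tibble::tibble(taxon_id = letters[1:8],
                                            module = 1L),
                summaries = tibble::tibble(module = 1L, size = 8L))
  enr_w <- module_enrichment(net, whole, calls)
  expect_true(all(enr_w$p == 1))
})

test_that("enrichment p-values are roughly uniform when classes are unstructured", {
  net <- make_net(c("a", "b", "c", "d", "e", "f", "g"),
                  c("b", "c", "d", "a", "f", "g", "h"))
  part <- list(membership = tibble::tibble(taxon_id = letters[1:8],
                                           module = rep(1:2, each = 4)),
               summaries = tibble::tibble(module = 1:2, size = c(4L, 4L)))
  set.seed(77)
  p_null <- vapply(1:200, function(i) {
    calls <- tibble::tibble(taxon_id = letters[1:8],
                            call = sample(rep(c("OMZ", "EPI"), each = 4)))
    module_enrichment(net, part, calls)$p[1]
  }, numeric(1))
  # one-sided test under the null: P(p <= t) <= t; check no inflation
  expect_lte(mean(p_null <= 0.05), 0.10)
  expect_gt(mean(p_null), 0.3)
})

test_that("topology metrics satisfy their identities on canonical graphs", {
  tri <- make_net(c("a", "a", "b"), c("b", "c", "c"))
  row <- topology_report(tri)
  expect_equal(row$avg_degree, 2)
  expect_equal(row$clustering, 1)
  expect_equal(row$density, 1)
  expect_equal(row$avg_path_length, 1)

  path3 <- make_net(c("a", "b"), c("b", "c"))
  rp <- topology_report(path3)
  expect_equal(rp$avg_degree, 4 / 3)
  expect_equal(rp$clustering, 0)
  expect_equal(rp$avg_path_length, 4 / 3)

  star <- make_net(rep("hub", 4), c("a", "b", "c", "d"))
  expect_equal(topology_report(star)$degree_centralization, 1)

  # identities on an arbitrary signed graph, plus per-module rows
  set.seed(9)
  sim <- generate_community(synthetic_design(n_stations = 12, n_omz_stations = 6,
                                             taxa_per_group = c(prokaryote = 30),
                                             n_modules = 2, module_taxa = 10,
                                             module_strength = 3, seed = 19))
  net <- infer_network(robust_clr(sim$otu), alpha = 0.05, max_k = 1)
  part <- cnm_modules(net)
  rep_all <- topology_report(net, part)
  glob <- rep_all[rep_all$graph == "global", ]
  E <- nrow(net$edges); N <- nrow(net$nodes)
  expect_equal(glob$avg_degree, 2 * E / N)
  expect_equal(glob$density, 2 * E / (N * (N - 1)))
  expect_equal(glob$positive_edges + glob$negative_edges, E)
})

test_that("positive edge share is the fraction of plus signs, label-invariant", {
  net <- make_net(c("a", "b", "c"), c("b", "c", "d"),
                  sign = c("+", "+", "-"))
  expect_equal(positive_edge_fraction(net), 2 / 3)
  relabeled <- net
  relabeled$edges$from <- paste0("x_", net$edges$from)
  relabeled$edges$to <- paste0("x_", net$edges$to)
  expect_equal(positive_edge_fraction(relabeled), 2 / 3)
  all_pos <- make_net(c("a", "b"), c("b", "c"))
  expect_equal(positive_edge_fraction(all_pos), 1)
})

test_that("planted module structure is recovered with high NMI", {
  nmis <- vapply(1:3, function(s) {
    des <- synthetic_design(
      n_stations = 25, n_omz_stations = 13,
      taxa_per_group = c(prokaryote = 120, picoeukaryote = 100, ncldv = 80),
      n_modules = 3, module_taxa = 30, module_strength = 3, seed = 400 + s)
    sim <- generate_community(des)
    net <- infer_network(robust_clr(sim$otu),
                         meta_variables = sim$otu$sample_meta$ecoregion,
                         alpha = 0.05, max_k = 1)
    part <- cnm_modules(net)
    tr <- sim$truth$taxa
    planted <- tr$taxon_id[tr$module > 0]
    common <- intersect(planted, part$membership$taxon_id)
    nmi(tr$module[match(common, tr$taxon_id)],
        part$membership$module[match(common, part$membership$taxon_id)])
  }, numeric(1))
  expect_true(all(nmis >= 0.8))
})
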