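# toy builders shared across test files

toy_otu <- function() {
  counts <- matrix(
    c(5L, 7L, 0L, 10L,
      0L, 4L, 2L, 1L,
      3L, 0L, 6L, 0L),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("t1", "t2", "t3"),
                    c("s1_SRF", "s1_DCM", "s1_MES", "s2_SRF")))
  otu_table(counts,
            taxon_meta = tibble::tibble(taxon_id = c("t1", "t2", "t3"),
                                        group = c("prokaryote", "ncldv", "phage")),
            sample_meta = tibble::tibble(
              sample_id = colnames(counts),
              station = c("s1", "s1", "s1", "s2"),
              layer = c("SRF", "DCM", "MES", "SRF"),
              o2_umol_kg = c(NA, NA, 150, NA)))
}

make_net <- function(from, to, sign = rep("+", length(from)),
                     weight = ifelse(sign == "+", 1, -1),
                     nodes = sort(unique(c(from, to)))) {
  structure(list(
    nodes = tibble::tibble(taxon_id = nodes),
    edges = tibble::tibble(from = from, to = to, weight = weight, sign = sign,
                           cond_set_size = 0L),
    alpha = 0.01, max_k = 3, n_samples = 0L, heterogeneous = FALSE),
    class = "signed_network")
}

# 6-node graph: two triangles joined by one bridge edge (7 edges)
bridge_graph <- function() {
  make_net(from = c("a", "a", "b", "c", "d", "d", "e"),
           to   = c("b", "c", "c", "d", "e", "f", "f"))
}

# all set partitions of 1..n (Bell(n) of them), as integer label vectors
set_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in set_partitions(n - 1)) {
    k <- max(p)
    for (m in seq_len(k + 1)) out[[length(out) + 1]] <- c(p, m)
  }
  out
}

# modularity of a labelled partition from first principles: Q = sum(e_cc - a_c^2)
modularity_by_hand <- function(net, labels) {
  ii <- match(net$edges$from, net$nodes$taxon_id)
  jj <- match(net$edges$to, net$nodes$taxon_id)
  m <- length(ii)
  q <- 0
  for (c_ in unique(labels)) {
    in_c <- which(labels == c_)
    e_cc <- sum(ii %in% in_c & jj %in% in_c) / m
    deg <- sum(ii %in% in_c) + sum(jj %in% in_c)
    q <- q + e_cc - (deg / (2 * m))^2
  }
  q
}

brute_force_best_q <- function(net) {
  n <- nrow(net$nodes)
  max(vapply(set_partitions(n), function(p) modularity_by_hand(net, p),
             numeric(1)))
}
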