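#' Greedy modularity (Clauset-Newman-Moore) module detection
#'
#' Agglomerative maximisation of Newman's modularity
#' \eqn{Q = \sum_c (e_{cc} - a_c^2)} on the unweighted, unsigned simple
#' graph: association signs are ignored for community structure (the
#' signed counts are reported per module by [topology_report()]). Each
#' node starts as its own module; at every step the connected module pair
#' with the largest modularity gain \eqn{\Delta Q = e_{ij} - 2 a_i a_j}
#' is merged, ties broken by the smallest (module id, module id) pair,
#' and merging stops when no merge increases Q.
#'
#' @param net a `signed_network` from [infer_network()], or an igraph
#'   object.
#' @return a `module_partition`: tibble `membership` (`taxon_id`,
#'   `module`; isolated nodes keep singleton modules), modularity `Q`,
#'   and a `summaries` tibble with per-module size and signed edge
#'   counts.
#' @export
cnm_modules <- function(net) {
  if (inherits(net, "igraph")) {
    edges_df <- igraph::as_data_frame(net, what = "edges")[, 1:2]
    names(edges_df) <- c("from", "to")
    node_ids <- igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net)))
    signs <- rep("+", nrow(edges_df))
  } else {
    edges_df <- net$edges
    node_ids <- net$nodes$taxon_id
    signs <- net$edges$sign
  }
  if (!nrow(edges_df)) abort("Cannot detect modules in a graph with no edges.")
  p <- length(node_ids)
  ii <- match(edges_df$from, node_ids)
  jj <- match(edges_df$to, node_ids)
  keep <- ii != jj
  ii <- ii[keep]; jj <- jj[keep]
  m <- length(ii)

  # e[a, b]: fraction of edges between current modules a and b
  e <- matrix(0, p, p)
  for (k in seq_len(m)) {
    a <- ii[k]; b <- jj[k]
    e[a, b] <- e[a, b] + 1 / m
    e[b, a] <- e[b, a] + 1 / m
  }
  a_frac <- rowSums(e) / 2 + diag(e) / 2   # degree fractions; diag holds 2*within/m
  diag_within <- numeric(p)                 # within-module edge fraction
  member <- seq_len(p)
  active <- sort(unique(c(ii, jj)))         # isolated nodes never merge

  repeat {
    best <- NULL; best_dq <- 0
    for (ai in seq_along(active)) {
      a <- active[ai]
      js <- active[active > a]
      js <- js[e[a, js] > 0]
      if (!length(js)) next
      dq <- e[a, js] - 2 * a_frac[a] * a_frac[js]
      w <- which(dq > best_dq + 1e-12)
      if (length(w)) {
        w1 <- w[which.max(dq[w])]
        # exact ties broken later by scanning order (smallest pair first)
        cand_dq <- dq[w1]
        if (cand_dq > best_dq + 1e-12) {
          best_dq <- cand_dq; best <- c(a, js[w1])
        }
      }
    }
    if (is.null(best)) break
    a <- best[1]; b <- best[2]
    diag_within[a] <- diag_within[a] + diag_within[b] + e[a, b]
    e[a, ] <- e[a, ] + e[b, ]
    e[, a] <- e[, a] + e[, b]
    e[a, a] <- 0
    e[b, ] <- 0; e[, b] <- 0
    a_frac[a] <- a_frac[a] + a_frac[b]
    a_frac[b] <- 0
    member[member == b] <- a
    active <- setdiff(active, b)
  }

  Q <- sum(diag_within[active] - a_frac[active]^2)
  module_id <- match(member, sort(unique(member)))
  membership <- tibble(taxon_id = node_ids, module = module_id)

  esign <- tibble(from = node_ids[ii], to = node_ids[jj], sign = signs[keep]) |>
    mutate(m_from = module_id[match(.data$from, node_ids)],
           m_to = module_id[match(.data$to, node_ids)])
  within <- esign |> filter(.data$m_from == .data$m_to)
  summaries <- membership |>
    dplyr::count(.data$module, name = "size") |>
    left_join(
      within |> group_by(module = .data$m_from) |>
        summarise(positive_edges = sum(.data$sign == "+"),
                  negative_edges = sum(.data$sign == "-"), .groups = "drop"),
      by = "module") |>
    mutate(positive_edges = dplyr::coalesce(.data$positive_edges, 0L),
           negative_edges = dplyr::coalesce(.data$negative_edges, 0L))

  structure(list(membership = membership, Q = Q, summaries = summaries),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  nm <- sum(x$summaries$size > 1)
  cat("Module partition: Q = ", round(x$Q, 4), "; ",
      nrow(x$summaries), " modules (", nm, " non-singleton)\n", sep = "")
  invisible(x)
}

#' Modularity Q of an explicit partition
#'
#' @param net a `signed_network` or igraph.
#' @param membership integer/character module assignment named by or
#'   ordered as the network's nodes.
#' @return modularity of the unsigned simple graph under that partition.
#' @export
modularity_q <- function(net, membership) {
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  igraph::modularity(g, as.integer(as.factor(membership)))
}

#' Eco-region enrichment of network modules (Fisher's exact test)
#'
#' For every module and eco-region class, a one-sided (enrichment)
#' Fisher's exact test on the 2x2 table of in-module/out-of-module versus
#' in-class/out-of-class node counts, BH-adjusted across all tested
#' (module, class) pairs.
#'
#' @param net a `signed_network`.
#' @param partition a `module_partition` from [cnm_modules()].
#' @param calls an `ecoregion_calls` tibble from [classify_otus()] (or
#'   any tibble with `taxon_id` and `call`) covering the network nodes.
#' @return tibble with the 2x2 counts, `odds_ratio`, one-sided `p` and
#'   `p_bh` per (module, class); classes absent from the network are
#'   skipped with a message.
#' @export
module_enrichment <- function(net, partition, calls) {
  calls <- as_tibble(calls)
  nodes <- net$nodes |>
    left_join(calls[, c("taxon_id", "call")], by = "taxon_id") |>
    left_join(partition$membership, by = "taxon_id")
  if (anyNA(nodes$call)) {
    abort(paste0("Eco-region calls missing for nodes: ",
                 paste(utils::head(nodes$taxon_id[is.na(nodes$call)], 5),
                       collapse = ", ")))
  }
  n_total <- nrow(nodes)
  classes <- sort(unique(calls$call))
  absent <- setdiff(classes, unique(nodes$call))
  if (length(absent)) {
    inform(paste0("Classes absent from the network, skipped: ",
                  paste(absent, collapse = ", ")))
    classes <- setdiff(classes, absent)
  }
  res <- purrr::map_dfr(sort(unique(nodes$module)), function(mod) {
    in_mod <- nodes$module == mod
    purrr::map_dfr(classes, function(cl) {
      a <- sum(in_mod & nodes$call == cl)
      b <- sum(in_mod & nodes$call != cl)
      c_ <- sum(!in_mod & nodes$call == cl)
      d <- n_total - a - b - c_
      ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                        alternative = "greater")
      tibble(module = mod, class = cl, in_class = a, in_other = b,
             out_class = c_, out_other = d,
             odds_ratio = unname(ft$estimate), p = ft$p.value)
    })
  })
  res$p_bh <- bh_adjust(res$p)
  res
}

freeman_centralization <- function(scores, max_sum) {
  if (max_sum <= 0) return(0)
  sum(max(scores) - scores) / max_sum
}

topology_row <- function(g, signs, label, partition_q = NA_real_) {
  N <- igraph::vcount(g)
  E <- igraph::ecount(g)
  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  centr_deg <- igraph::centr_degree(g, loops = FALSE)$centralization
  centr_btw <- igraph::centr_betw(g, directed = FALSE)$centralization
  tibble(
    graph = label, nodes = N,
    positive_edges = sum(signs == "+"), negative_edges = sum(signs == "-"),
    avg_degree = 2 * E / N,
    clustering = mean(local_cc),
    density = if (N > 1) 2 * E / (N * (N - 1)) else 0,
    avg_path_length = igraph::mean_distance(g, unconnected = TRUE),
    degree_centralization = centr_deg,
    betweenness_centralization = centr_btw,
    modularity = partition_q)
}

#' Network topology report (global and per-module)
#'
#' Computes, for the whole graph and optionally for every module's
#' induced subgraph: node and signed edge counts, average degree
#' \eqn{2E/N}, mean local clustering coefficient (nodes of degree < 2
#' contribute 0), density \eqn{2E/N(N-1)}, average shortest-path length
#' over connected pairs only, Freeman degree and betweenness
#' centralizations, and modularity — Q of the supplied partition for the
#' global row, and Q of a fresh greedy partition of each module-induced
#' subgraph for module rows.
#'
#' @param net a `signed_network`.
#' @param partition optional `module_partition`; when given, per-module
#'   rows are added for non-singleton modules.
#' @param min_module_size smallest module to report individually
#'   (default 3).
#' @return tibble, one row per graph.
#' @export
topology_report <- function(net, partition = NULL, min_module_size = 3) {
  if (!nrow(net$edges)) abort("Empty graph.")
  g <- as_igraph(net)
  q_global <- if (!is.null(partition)) {
    modularity_q(net, partition$membership$module[
      match(net$nodes$taxon_id, partition$membership$taxon_id)])
  } else NA_real_
  out <- topology_row(g, net$edges$sign, "global", q_global)
  if (!is.null(partition)) {
    mods <- partition$summaries$module[partition$summaries$size >= min_module_size]
    for (mod in mods) {
      ids <- partition$membership$taxon_id[partition$membership$module == mod]
      sub <- igraph::induced_subgraph(g, ids)
      in_mod <- net$edges$from %in% ids & net$edges$to %in% ids
      sub_q <- if (igraph::ecount(sub) > 0) {
        sub_net <- list(nodes = tibble(taxon_id = ids),
                        edges = net$edges[in_mod, ])
        cnm_modules(structure(sub_net, class = "signed_network"))$Q
      } else NA_real_
      out <- bind_rows(out, topology_row(sub, net$edges$sign[in_mod],
                                         paste0("module_", mod), sub_q))
    }
  }
  out
}

#' Normalized mutual information between two partitions
#'
#' \eqn{NMI = 2 I(A; B) / (H(A) + H(B))}; 1 for identical partitions
#' (up to relabelling), 0 for independent ones. Used to score recovery
#' of planted modules.
#'
#' @param a,b partition labels over the same elements.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nz <- pij > 0
  I <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  H <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  ha <- H(pi_); hb <- H(pj_)
  if (ha + hb == 0) return(1)
  2 * I / (ha + hb)
}
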