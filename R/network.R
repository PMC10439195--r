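fisher_z_significant <- function(r, n, s, z_crit) {
  r <- min(max(r, -1 + 1e-12), 1 - 1e-12)
  df <- n - s - 3
  if (df <= 0) return(TRUE)   # too few samples to reject dependence
  abs(atanh(r)) * sqrt(df) > z_crit
}

partial_cor <- function(R, i, j, S) {
  if (length(S) == 1) {
    den <- (1 - R[i, S]^2) * (1 - R[j, S]^2)
    if (den <= 0) return(0)
    return((R[i, j] - R[i, S] * R[j, S]) / sqrt(den))
  }
  idx <- c(i, j, S)
  P <- tryCatch(solve(R[idx, idx, drop = FALSE]), error = function(e) NULL)
  if (is.null(P)) return(0)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

#' Infer a signed co-occurrence network by conditional-independence tests
#'
#' Local-to-global constraint-based learning on CLR-transformed
#' abundances, which are treated as approximately multivariate Gaussian.
#' Every taxon pair starts from its Pearson correlation, tested with the
#' Fisher z statistic \eqn{\mathrm{atanh}(r)\sqrt{n - |S| - 3}} against a
#' standard normal at level `alpha`. Surviving edges are then challenged
#' by partial correlations given conditioning sets `S` drawn from the
#' current neighbourhoods of the two endpoints (candidates ordered by
#' absolute marginal correlation, descending, so inference is
#' deterministic), up to size `max_k`; an edge is removed as soon as one
#' set renders the pair conditionally independent. Removals are applied
#' between levels (PC-stable style) so the result does not depend on taxa
#' ordering. In heterogeneous mode, one-hot indicator variables built
#' from `meta_variables` (e.g. the sample eco-region) are always
#' candidate conditioning variables, which strips out edges that merely
#' reflect a shared habitat response; the indicators themselves are not
#' nodes.
#'
#' The retained edge weight is the partial correlation given the largest
#' conditioning set the edge survived (the marginal correlation for
#' never-conditioned edges); its sign is the edge sign.
#'
#' @param clr a `clr_matrix` from [robust_clr()] or numeric matrix
#'   (taxa x samples).
#' @param meta_variables optional data frame or vector of per-sample
#'   categorical covariates; supplying it switches on heterogeneous mode.
#' @param alpha significance level of the independence tests
#'   (default 0.01).
#' @param max_k maximum conditioning-set size (default 3).
#' @param node_meta optional tibble with `taxon_id` plus annotation
#'   columns (group, eco-region call) copied onto the nodes.
#' @return a `signed_network`: list with `nodes` and `edges` tibbles
#'   (`from`, `to`, `weight`, `sign`, `cond_set_size`), plus `alpha`,
#'   `max_k`, `n_samples`. Constant taxa are excluded with a warning.
#' @export
infer_network <- function(clr, meta_variables = NULL, alpha = 0.01, max_k = 3,
                          node_meta = NULL) {
  X <- clr_values(clr)
  n <- ncol(X)
  if (n < max_k + 4) abort("Too few samples for the requested max_k.")
  taxa <- rownames(X) %||% paste0("t", seq_len(nrow(X)))
  const <- apply(X, 1, sd) == 0
  if (any(const)) {
    warn(paste0("Constant taxa excluded: ", paste(taxa[const], collapse = ", ")))
    X <- X[!const, , drop = FALSE]
    taxa <- taxa[!const]
  }
  p <- nrow(X)
  feats <- t(X)

  meta_idx <- integer(0)
  if (!is.null(meta_variables)) {
    mv <- as.data.frame(meta_variables)
    onehot <- do.call(cbind, lapply(mv, function(v) {
      v <- as.factor(v)
      m <- stats::model.matrix(~ v - 1)
      m[, apply(m, 2, sd) > 0, drop = FALSE]
    }))
    if (!is.null(onehot) && ncol(onehot)) {
      meta_idx <- p + seq_len(ncol(onehot))
      feats <- cbind(feats, onehot)
    }
  }
  R <- suppressWarnings(cor(feats))
  R[!is.finite(R)] <- 0
  z_crit <- qnorm(1 - alpha / 2)

  # level 0: marginal screening over taxa pairs (vectorised Fisher z)
  Rt <- R[seq_len(p), seq_len(p), drop = FALSE]
  Rc <- pmin(pmax(Rt, -1 + 1e-12), 1 - 1e-12)
  adj <- abs(atanh(Rc)) * sqrt(max(n - 3, 0)) > z_crit
  diag(adj) <- FALSE
  weight <- ifelse(adj, Rt, 0)
  cond_size <- matrix(0L, p, p)

  for (lev in seq_len(max_k)) {
    edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
    if (!nrow(edges)) break
    remove <- matrix(FALSE, p, p)
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      nb <- union(which(adj[i, ]), which(adj[j, ]))
      cand <- union(setdiff(nb, c(i, j)), meta_idx)
      if (length(cand) < lev) next
      strength <- pmax(abs(R[cand, i]), abs(R[cand, j]))
      cand <- cand[order(-strength, cand)]
      # combn(x, m) on a length-1 integer would expand seq_len(x)
      subsets <- if (length(cand) == lev) list(cand) else combn(cand, lev, simplify = FALSE)
      survived_pc <- NA_real_
      gone <- FALSE
      for (S in subsets) {
        pc <- partial_cor(R, i, j, S)
        if (!fisher_z_significant(pc, n, lev, z_crit)) {
          gone <- TRUE
          break
        }
        if (is.na(survived_pc)) survived_pc <- pc   # first subset in order
      }
      if (gone) {
        remove[i, j] <- TRUE
      } else if (!is.na(survived_pc)) {
        weight[i, j] <- weight[j, i] <- survived_pc
        cond_size[i, j] <- cond_size[j, i] <- lev
      }
    }
    # PC-stable: drop all failed edges only after the level completes
    adj[remove | t(remove)] <- FALSE
  }

  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  w <- weight[idx]
  edges <- tibble(
    from = taxa[idx[, 1]], to = taxa[idx[, 2]],
    weight = w, sign = ifelse(w >= 0, "+", "-"),
    cond_set_size = cond_size[idx])
  nodes <- tibble(taxon_id = taxa)
  if (!is.null(node_meta)) nodes <- left_join(nodes, as_tibble(node_meta), by = "taxon_id")
  structure(list(nodes = nodes, edges = edges, alpha = alpha, max_k = max_k,
                 n_samples = n, heterogeneous = length(meta_idx) > 0),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat("<signed_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges (",
      sum(x$edges$sign == "+"), " positive, ", sum(x$edges$sign == "-"),
      " negative); alpha = ", x$alpha, ", max_k = ", x$max_k, "\n", sep = "")
  invisible(x)
}

#' Share of positive associations in a signed network
#'
#' @param net a `signed_network` (or any list with an `edges` tibble
#'   carrying a `sign` column).
#' @return fraction of edges with positive sign, in `[0, 1]`.
#' @export
positive_edge_fraction <- function(net) {
  e <- net$edges
  if (!nrow(e)) abort("Network has no edges.")
  mean(e$sign == "+")
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("from", "to")], directed = FALSE,
                                vertices = net$nodes$taxon_id)
}

#' Export the edge list of a signed network to TSV
#'
#' @param net a `signed_network`.
#' @param path output file.
#' @export
write_edge_list <- function(net, path) {
  readr::write_tsv(net$edges, path)
  invisible(path)
}
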