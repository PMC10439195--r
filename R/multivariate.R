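as_dist_checked <- function(d) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (nrow(m) != ncol(m)) abort("`d` must be a dist object or square matrix.")
    d <- stats::as.dist(m)
  }
  d
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Best-of-restarts NMDS minimising Kruskal stress-1; the workhorse is
#' `vegan::metaMDS()` on the supplied dissimilarities (no internal
#' transformation), seeded explicitly for reproducibility.
#'
#' @param d a [stats::dist] (e.g. from [bray_curtis()]).
#' @param k embedding dimension (default 2).
#' @param n_restarts random restarts; the lowest-stress solution is kept.
#' @param max_iter iteration cap per restart.
#' @param seed integer RNG seed.
#' @return an `nmds_result` with `coordinates` (tibble: sample_id + axes),
#'   `stress` (in `[0, 1]`), `converged`, `n_restarts`, `seed`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 500, seed = 1) {
  d <- as_dist_checked(d)
  n <- attr(d, "Size")
  if (k >= n) abort("`k` must be smaller than the number of samples.")
  fit <- withr::with_seed(seed, suppressWarnings(suppressMessages(
    vegan::metaMDS(d, k = k, try = n_restarts, trymax = n_restarts,
                   maxit = max_iter, trace = 0, autotransform = FALSE,
                   wascores = FALSE)
  )))
  ids <- attr(d, "Labels") %||% as.character(seq_len(n))
  coords <- as_tibble(fit$points, .name_repair = "minimal")
  names(coords) <- paste0("NMDS", seq_len(k))
  structure(list(coordinates = bind_cols(tibble(sample_id = ids), coords),
                 stress = fit$stress, converged = fit$converged > 0,
                 n_restarts = n_restarts, seed = seed),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat("NMDS: stress = ", signif(x$stress, 4), ", ",
      nrow(x$coordinates), " samples, ",
      if (x$converged) "converged" else "no convergent solution",
      " (", x$n_restarts, " restarts)\n", sep = "")
  invisible(x)
}

gower_center <- function(d) {
  A <- -0.5 * as.matrix(d)^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

# distance from each sample to its own group centroid in principal-coordinate
# space, via the Gower-centered inner-product matrix:
#   d^2(j, c_S) = G_jj - (2/|S|) sum_k G_jk + (1/|S|^2) sum_kl G_kl.
# Axes with negative eigenvalues enter with a negative sign, which is the
# standard imaginary-axis correction; residual negative squares are clipped
# to zero before the square root.
centroid_distances <- function(G, groups) {
  out <- numeric(nrow(G))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    cross <- rowMeans(G[, idx, drop = FALSE])
    cc <- mean(G[idx, idx])
    d2 <- diag(G) - 2 * cross + cc
    out[idx] <- sqrt(pmax(d2[idx], 0))
  }
  out
}

dispersion_F <- function(G, groups) {
  dv <- centroid_distances(G, groups)
  gm <- tapply(dv, groups, mean)
  ng <- tapply(dv, groups, length)
  ss_among <- sum(ng * (gm - mean(dv))^2)
  ss_within <- sum((dv - gm[groups])^2)
  k <- length(gm)
  if (ss_within <= .Machine$double.eps) return(Inf)
  (ss_among / (k - 1)) / (ss_within / (length(dv) - k))
}

#' Homogeneity of multivariate dispersions
#'
#' Embeds the dissimilarity matrix by principal coordinates (negative
#' eigenvalues handled by the standard imaginary-axis correction, worked
#' directly on the Gower-centered inner-product matrix), measures each
#' sample's distance to its group centroid, and tests equality of mean
#' dispersion across groups with a one-way F statistic. The permutation
#' p-value re-derives centroids and distances under every relabelling,
#' so the test is exact under exchangeability; p uses the
#' \eqn{(1 + \#\{F^* \ge F\}) / (1 + B)} estimator. The observed
#' distances coincide with `vegan::betadisper(type = "centroid")`.
#'
#' @param d a [stats::dist].
#' @param groups group labels, one per sample.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer RNG seed.
#' @return a `dispersion_result` with per-sample distances, group means,
#'   `F_disp`, `p_perm`, and a `degenerate` flag (all-identical input
#'   gives all-zero distances and `p = 1`).
#' @export
dispersion_test <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as_dist_checked(d)
  groups <- as.factor(groups)
  if (length(groups) != attr(d, "Size")) abort("One group label per sample required.")
  if (nlevels(droplevels(groups)) < 2) abort("Need at least two groups.")
  if (all(table(groups) < 2)) abort("All groups are singletons.")
  ids <- attr(d, "Labels") %||% as.character(seq_along(groups))

  if (max(d) == 0) {
    return(structure(list(
      distances = tibble(sample_id = ids, group = as.character(groups),
                         dist_to_centroid = 0),
      group_means = tibble(group = levels(groups), mean_dist = 0),
      F_disp = NA_real_, p_perm = 1, n_perm = n_perm, seed = seed,
      degenerate = TRUE), class = "dispersion_result"))
  }
  G <- gower_center(d)
  gchar <- as.character(groups)
  dv <- centroid_distances(G, gchar)
  F_obs <- dispersion_F(G, gchar)
  hits <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      dispersion_F(G, sample(gchar)) >= F_obs
    }, logical(1)))
  })
  structure(list(
    distances = tibble(sample_id = ids, group = gchar,
                       dist_to_centroid = dv),
    group_means = tibble(group = levels(groups),
                         mean_dist = as.numeric(tapply(dv, groups, mean))),
    F_disp = F_obs, p_perm = (1 + hits) / (1 + n_perm),
    n_perm = n_perm, seed = seed,
    degenerate = FALSE), class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("Multivariate dispersion test: F = ", signif(x$F_disp, 4),
      ", permutation p = ", signif(x$p_perm, 4),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

ss_within_groups <- function(d2, groups) {
  ss <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss <- ss + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss
}

unique_perms <- function(x) {
  # all distinct permutations of a label vector (small n only)
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (v in unique(x)) {
    rest <- x[-match(v, x)]
    for (p in unique_perms(rest)) out[[length(out) + 1]] <- c(v, p)
  }
  out
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squared dissimilarities into among- and
#' within-group components using the identity
#' \eqn{SS_{total} = \sum_{j<k} d_{jk}^2 / n} and
#' \eqn{SS_{within} = \sum_g \sum_{j<k \in g} d_{jk}^2 / n_g}, forms the
#' pseudo-F ratio, and estimates the p-value by permuting group labels
#' with the \eqn{(1 + \#\{F^* \ge F\}) / (1 + B)} estimator. When the
#' residual sum of squares is exactly zero the pseudo-F is reported as
#' `Inf`.
#'
#' @param d a [stats::dist].
#' @param groups group labels, one per sample.
#' @param n_perm number of permutations (default 999).
#' @param seed integer RNG seed.
#' @param exact if `TRUE`, enumerate every distinct arrangement of the
#'   label vector instead of sampling (small n only); the p-value is then
#'   the exact fraction of arrangements with `F* >= F`.
#' @return a `permanova_result` with df, sums of squares, `pseudo_F`,
#'   `R2 = SS_among / SS_total` and `p_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1, exact = FALSE) {
  d <- as_dist_checked(d)
  groups <- as.character(groups)
  n <- attr(d, "Size")
  if (length(groups) != n) abort("One group label per sample required.")
  g <- length(unique(groups))
  if (g < 2) abort("All samples in one group; nothing to test.")
  if (any(table(groups) < 2)) warn("Groups with a single member inflate residual df.")

  d2 <- as.matrix(d)^2
  ss_total <- sum(d2) / (2 * n)
  ss_resid <- ss_within_groups(d2, groups)
  ss_among <- ss_total - ss_resid
  df_among <- g - 1
  df_resid <- n - g
  f_stat <- function(ssr) {
    if (ssr <= .Machine$double.eps * ss_total) return(Inf)
    (ss_total - ssr) / df_among / (ssr / df_resid)
  }
  F_obs <- f_stat(ss_resid)

  if (exact) {
    perms <- unique_perms(groups)
    F_perm <- vapply(perms, function(p) f_stat(ss_within_groups(d2, p)), numeric(1))
    p <- mean(F_perm >= F_obs)
    n_perm <- length(perms)
  } else {
    hits <- withr::with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        f_stat(ss_within_groups(d2, sample(groups))) >= F_obs
      }, logical(1)))
    })
    p <- (1 + hits) / (1 + n_perm)
  }
  structure(list(df_among = df_among, df_resid = df_resid,
                 ss_among = ss_among, ss_resid = ss_resid, ss_total = ss_total,
                 pseudo_F = F_obs, R2 = ss_among / ss_total,
                 p_perm = p, n_perm = n_perm, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA: pseudo-F = ", signif(x$pseudo_F, 4),
      " (df ", x$df_among, ", ", x$df_resid, "), R2 = ", signif(x$R2, 4),
      ", p = ", signif(x$p_perm, 4), " [", x$n_perm, " perms]\n", sep = "")
  invisible(x)
}

env_matrix <- function(env, variables = NULL) {
  env <- as_tibble(env)
  num <- env[vapply(env, is.numeric, logical(1))]
  if (!is.null(variables)) num <- num[variables]
  const <- vapply(num, function(v) sd(v) == 0, logical(1))
  if (any(const)) {
    abort(paste0("Constant environmental variables cannot constrain an ordination: ",
                 paste(names(num)[const], collapse = ", ")))
  }
  as.data.frame(num)
}

#' Variance inflation factors of environmental constraint variables
#'
#' `VIF_v = 1 / (1 - R^2_v)` where `R^2_v` comes from regressing variable
#' `v` on all the others. Perfectly collinear variables are reported as
#' `Inf`.
#'
#' @param env data frame of numeric environmental variables (a
#'   `sample_id` column, if present, is ignored).
#' @param variables optional variable selection.
#' @return named numeric vector of VIFs (all `>= 1`).
#' @export
vif_scores <- function(env, variables = NULL) {
  X <- env_matrix(env, variables)
  if (ncol(X) < 2) abort("Need at least two variables for VIF.")
  vapply(names(X), function(v) {
    # a perfect fit (collinear variable) is an expected path reported as Inf
    r2 <- suppressWarnings(
      summary(lm(X[[v]] ~ ., data = X[setdiff(names(X), v)]))$r.squared)
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Constrained ordination of a community matrix on environmental variables
#'
#' Default method is redundancy analysis (RDA) of the CLR community
#' matrix on standardized constraints: CLR values can be negative, which
#' canonical correspondence analysis (CCA) cannot accept. `method =
#' "cca"` is available for non-negative data; `literal = TRUE` min-shifts
#' a CLR matrix to non-negative values first so the CCA route can be
#' exercised on transformed data. The global significance of the
#' constraints is tested by permuting sample rows of the response.
#'
#' @param response a `clr_matrix`, an [otu_table()] (relative abundances
#'   are used), or a numeric matrix (taxa x samples).
#' @param env data frame of environmental variables aligned with samples
#'   (optional `sample_id` column is dropped).
#' @param method `"rda"` (default) or `"cca"`.
#' @param n_perm permutations for the global test.
#' @param seed integer RNG seed.
#' @param variables optional constraint selection.
#' @param literal min-shift negative response values so CCA applies.
#' @return an `ordination_result` with `constrained_proportion`,
#'   per-axis proportions, site and biplot scores, VIFs and the global
#'   permutation p-value.
#' @export
constrained_ordination <- function(response, env, method = c("rda", "cca"),
                                   n_perm = 999, seed = 1, variables = NULL,
                                   literal = FALSE) {
  method <- match.arg(method)
  Y <- t(response_matrix(response))
  if (method == "cca" && any(Y < 0)) {
    if (!literal) {
      abort("CCA requires non-negative data; use method = 'rda' for CLR values or literal = TRUE to min-shift.")
    }
    Y <- Y - min(Y)
  }
  X <- env_matrix(env, variables)
  if (nrow(X) != nrow(Y)) abort("Samples of `response` and `env` do not align.")
  Xs <- as.data.frame(scale(X))
  mod <- if (method == "rda") {
    vegan::rda(Y ~ ., data = Xs)
  } else {
    vegan::cca(Y ~ ., data = Xs)
  }
  vifs <- if (ncol(X) >= 2) vif_scores(X) else setNames(1, names(X))
  glob <- withr::with_seed(seed, anova(mod, permutations = n_perm))
  axis_prop <- mod$CCA$eig / mod$tot.chi
  structure(list(
    method = method,
    constrained_proportion = mod$CCA$tot.chi / mod$tot.chi,
    axis_proportions = axis_prop,
    site_scores = vegan::scores(mod, display = "sites"),
    biplot_scores = vegan::scores(mod, display = "bp"),
    vif = vifs,
    global_p = glob$`Pr(>F)`[1],
    n_perm = n_perm, seed = seed, model = mod),
    class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(toupper(x$method), ": constraints explain ",
      round(100 * x$constrained_proportion, 1),
      "% of community variation (global permutation p = ",
      signif(x$global_p, 3), ")\n", sep = "")
  cat("VIF: ", paste(names(x$vif), signif(x$vif, 3), sep = "=", collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

response_matrix <- function(response) {
  if (inherits(response, "clr_matrix")) return(response$values)
  if (inherits(response, "otu_table")) return(relative_abundance(response))
  as.matrix(response)
}

#' Marginal permutation tests for each environmental variable
#'
#' Tests every constraint variable with all the others held as
#' conditioning covariables (order-independent, the `by = "margin"`
#' scheme of `vegan::anova.cca` with residual permutation under the
#' reduced model). Variables flagged as perfectly collinear by
#' [vif_scores()] get `NA` with a warning, since their marginal effect is
#' not identifiable.
#'
#' @inheritParams constrained_ordination
#' @return tibble with `variable` and permutation `p` columns.
#' @export
marginal_terms_test <- function(response, env, method = c("rda", "cca"),
                                n_perm = 999, seed = 1, variables = NULL,
                                literal = FALSE) {
  method <- match.arg(method)
  Y <- t(response_matrix(response))
  if (method == "cca" && any(Y < 0)) {
    if (!literal) abort("CCA requires non-negative data (see constrained_ordination).")
    Y <- Y - min(Y)
  }
  X <- env_matrix(env, variables)
  Xs <- as.data.frame(scale(X))
  vifs <- if (ncol(X) >= 2) vif_scores(X) else setNames(1, names(X))
  collinear <- names(vifs)[!is.finite(vifs)]
  if (length(collinear)) {
    warn(paste0("Collinear variables, marginal p set to NA: ",
                paste(collinear, collapse = ", ")))
  }
  mod <- if (method == "rda") vegan::rda(Y ~ ., data = Xs) else vegan::cca(Y ~ ., data = Xs)
  an <- withr::with_seed(seed, anova(mod, by = "margin", permutations = n_perm))
  p <- an$`Pr(>F)`
  names(p) <- rownames(an)
  out <- tibble(variable = names(X),
                p = as.numeric(p[names(X)]))
  out$p[out$variable %in% collinear] <- NA_real_
  out
}
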