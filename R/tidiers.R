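#' Tidiers for mesoniche result objects
#'
#' broom-style `tidy()` and `glance()` methods: `tidy()` returns the
#' per-unit table (coordinates, distances, scores, edges, memberships),
#' `glance()` a one-row model summary.
#'
#' @param x a result object.
#' @param ... unused.
#' @return a tibble.
#' @name mesoniche-tidiers
NULL

#' @rdname mesoniche-tidiers
#' @export
tidy.nmds_result <- function(x, ...) x$coordinates

#' @rdname mesoniche-tidiers
#' @export
glance.nmds_result <- function(x, ...) {
  tibble(stress = x$stress, converged = x$converged,
         n_restarts = x$n_restarts, seed = x$seed)
}

#' @rdname mesoniche-tidiers
#' @export
tidy.permanova_result <- function(x, ...) {
  tibble(term = c("groups", "residual", "total"),
         df = c(x$df_among, x$df_resid, x$df_among + x$df_resid),
         ss = c(x$ss_among, x$ss_resid, x$ss_total),
         pseudo_F = c(x$pseudo_F, NA, NA),
         R2 = c(x$R2, 1 - x$R2, 1),
         p = c(x$p_perm, NA, NA))
}

#' @rdname mesoniche-tidiers
#' @export
glance.permanova_result <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, R2 = x$R2, p = x$p_perm,
         n_perm = x$n_perm, seed = x$seed)
}

#' @rdname mesoniche-tidiers
#' @export
tidy.dispersion_result <- function(x, ...) x$distances

#' @rdname mesoniche-tidiers
#' @export
glance.dispersion_result <- function(x, ...) {
  tibble(F_disp = x$F_disp, p = x$p_perm, n_perm = x$n_perm,
         degenerate = x$degenerate)
}

#' @rdname mesoniche-tidiers
#' @export
tidy.ordination_result <- function(x, ...) {
  as_tibble(x$biplot_scores, rownames = "variable") |>
    mutate(vif = as.numeric(x$vif[.data$variable]))
}

#' @rdname mesoniche-tidiers
#' @export
glance.ordination_result <- function(x, ...) {
  tibble(method = x$method,
         constrained_proportion = x$constrained_proportion,
         global_p = x$global_p, n_perm = x$n_perm)
}

#' @rdname mesoniche-tidiers
#' @export
tidy.signed_network <- function(x, ...) x$edges

#' @rdname mesoniche-tidiers
#' @export
glance.signed_network <- function(x, ...) {
  tibble(nodes = nrow(x$nodes), edges = nrow(x$edges),
         positive_fraction = if (nrow(x$edges)) positive_edge_fraction(x) else NA_real_,
         alpha = x$alpha, max_k = x$max_k, n_samples = x$n_samples)
}

#' @rdname mesoniche-tidiers
#' @export
tidy.module_partition <- function(x, ...) x$membership

#' @rdname mesoniche-tidiers
#' @export
glance.module_partition <- function(x, ...) {
  tibble(Q = x$Q, n_modules = nrow(x$summaries),
         largest = max(x$summaries$size))
}
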