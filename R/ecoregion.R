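#' Kruskal-Wallis rank-sum test (tie-corrected)
#'
#' Ranks all observations together (midranks for ties) and computes
#' \deqn{H = \frac{12}{N(N+1)} \sum_g R_g^2 / n_g - 3(N+1)} divided by the
#' tie correction \eqn{1 - \sum_t (t^3 - t) / (N^3 - N)}. The p-value is
#' the upper chi-square tail with `g - 1` degrees of freedom. A fully
#' tied input (all values equal) returns `H = 0`, `p = 1` by convention.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`.
#' @return list with `H`, `p`, `df` and a `mean_ranks` tibble.
#' @export
#' @examples
#' kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3))$H  # 7.2
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) abort("Need at least two groups.")
  N <- length(values)
  if (N < 2 || length(groups) != N) abort("Need >= 2 observations with matching labels.")
  r <- rank(values)
  Rg <- tapply(r, groups, sum)
  ng <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  g <- nlevels(droplevels(groups))
  mean_ranks <- tibble(group = names(Rg), n = as.integer(ng),
                       mean_rank = as.numeric(Rg / ng))
  if (tie_corr <= 0) {   # every value identical
    return(list(H = 0, p = 1, df = g - 1, mean_ranks = mean_ranks))
  }
  H <- (12 / (N * (N + 1)) * sum(Rg^2 / ng) - 3 * (N + 1)) / tie_corr
  list(H = as.numeric(H), p = pchisq(H, g - 1, lower.tail = FALSE),
       df = g - 1, mean_ranks = mean_ranks)
}

#' Dunn's post-hoc pairwise test on joint ranks
#'
#' For each pair of groups (taken in factor-level order) the statistic is
#' \deqn{z = \frac{\bar R_b - \bar R_a}{\sqrt{\left[\frac{N(N+1)}{12} -
#' \frac{\sum_t (t^3 - t)}{12(N-1)}\right]\left(\frac{1}{n_a} +
#' \frac{1}{n_b}\right)}}} with mean ranks from the pooled ranking of all
#' observations, so `z > 0` means the second (later-level) group sits
#' higher. Two-sided normal p-values; `p_bh` adds a Benjamini-Hochberg
#' adjustment across the pairs of this call. A zero rank variance (all
#' observations tied) gives `z = 0`, `p = 1`.
#'
#' @inheritParams kruskal_wallis
#' @return tibble with `group1`, `group2`, `z`, `p`, `p_bh`; mean ranks
#'   are attached as the `"mean_ranks"` attribute.
#' @export
dunn_test <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  ng <- table(groups)
  if (any(ng == 0)) abort("Empty group.")
  if (nlevels(groups) < 2) abort("Need at least two groups.")
  N <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  ties <- table(values)
  v <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- combn(levels(groups), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se2 <- v * (1 / ng[[a]] + 1 / ng[[b]])
    z <- if (se2 <= 0) 0 else (mean_ranks[[b]] - mean_ranks[[a]]) / sqrt(se2)
    tibble(group1 = a, group2 = b, z = as.numeric(z),
           p = if (se2 <= 0) 1 else 2 * pnorm(-abs(z)))
  })
  res$p_bh <- bh_adjust(res$p)
  attr(res, "mean_ranks") <- tibble(group = names(mean_ranks),
                                    mean_rank = as.numeric(mean_ranks))
  res
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, kept as a named
#' step of the classification procedure.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Classify OTUs into eco-regions by Kruskal-Wallis + Dunn decision rules
#'
#' Each taxon's CLR abundances are compared across the three sample
#' eco-regions (EPI, OXIC_MES, OMZ). Taxa whose Kruskal-Wallis p-value,
#' BH-adjusted across taxa, exceeds `alpha` are called `UBIQUITOUS`.
#' Otherwise Dunn's pairwise tests decide: the *elected* region is the one
#' with the highest mean rank, and the taxon is assigned to it only when
#' it differs significantly from **both** other regions. Taxa whose two
#' mesopelagic regions are indistinguishable from each other, but each
#' elevated above EPI, are `CORE_MES`. Any other significant-but-
#' unresolvable pattern falls back to `UBIQUITOUS` with a
#' `non_resolvable` flag rather than being silently mis-assigned.
#'
#' @param clr a `clr_matrix` from [robust_clr()] (or numeric matrix,
#'   taxa x samples).
#' @param sample_ecoregions character vector of per-sample labels among
#'   `"EPI"`, `"OXIC_MES"`, `"OMZ"` (e.g. from
#'   [label_sample_ecoregions()]). Only stations with both epipelagic and
#'   mesopelagic samples should be included.
#' @param alpha significance level (default 0.05).
#' @param adjust_dunn BH-adjust the three Dunn p-values within each taxon
#'   before comparing to `alpha` (default `TRUE`).
#' @return tibble of class `ecoregion_calls`: one row per taxon with `H`,
#'   `p_kw`, `p_kw_bh`, pairwise `z_`/`p_` columns, `elected`, `call` and
#'   `non_resolvable`.
#' @export
classify_otus <- function(clr, sample_ecoregions, alpha = 0.05,
                          adjust_dunn = TRUE) {
  vals <- clr_values(clr)
  eco <- as.character(sample_ecoregions)
  if (length(eco) != ncol(vals)) abort("One eco-region label per sample required.")
  if (anyNA(eco)) abort("Missing eco-region labels; run label_sample_ecoregions() first.")
  regions <- c("EPI", "OXIC_MES", "OMZ")
  bad <- setdiff(unique(eco), regions)
  if (length(bad)) abort(paste0("Unknown eco-region labels: ", paste(bad, collapse = ", ")))
  eco <- factor(eco, levels = regions)

  taxa <- rownames(vals) %||% as.character(seq_len(nrow(vals)))
  kw <- purrr::map(seq_len(nrow(vals)), function(i) kruskal_wallis(vals[i, ], eco))
  p_kw <- vapply(kw, `[[`, numeric(1), "p")
  p_bh <- bh_adjust(p_kw)

  pair_key <- function(a, b) paste0(tolower(a), "_vs_", tolower(b))
  rows <- purrr::map_dfr(seq_len(nrow(vals)), function(i) {
    out <- tibble(taxon_id = taxa[i], H = kw[[i]]$H, p_kw = p_kw[i],
                  p_kw_bh = p_bh[i])
    dz <- dp <- setNames(rep(NA_real_, 3),
                         c(pair_key("EPI", "OXIC_MES"), pair_key("EPI", "OMZ"),
                           pair_key("OXIC_MES", "OMZ")))
    elected <- NA_character_; call <- "UBIQUITOUS"; flag <- FALSE
    if (p_bh[i] <= alpha) {
      dn <- dunn_test(vals[i, ], eco)
      key <- pair_key(dn$group1, dn$group2)
      dz[key] <- dn$z
      dp[key] <- if (adjust_dunn) dn$p_bh else dn$p
      mr <- attr(dn, "mean_ranks")
      elected <- mr$group[which.max(mr$mean_rank)]
      sig <- function(a, b) {
        k <- if (pair_key(a, b) %in% names(dp)) pair_key(a, b) else pair_key(b, a)
        !is.na(dp[[k]]) && dp[[k]] <= alpha
      }
      others <- setdiff(regions, elected)
      if (sig(elected, others[1]) && sig(elected, others[2])) {
        call <- elected
      } else if (!sig("OXIC_MES", "OMZ") &&
                 sig("EPI", "OXIC_MES") && sig("EPI", "OMZ") &&
                 mr$mean_rank[mr$group == "OXIC_MES"] > mr$mean_rank[mr$group == "EPI"] &&
                 mr$mean_rank[mr$group == "OMZ"] > mr$mean_rank[mr$group == "EPI"]) {
        call <- "CORE_MES"
      } else {
        call <- "UBIQUITOUS"; flag <- TRUE
      }
    }
    out[paste0("z_", names(dz))] <- as.list(dz)
    out[paste0("p_", names(dp))] <- as.list(dp)
    out$elected <- elected
    out$call <- call
    out$non_resolvable <- flag
    out
  })
  class(rows) <- c("ecoregion_calls", class(rows))
  attr(rows, "alpha") <- alpha
  rows
}

#' @export
print.ecoregion_calls <- function(x, ...) {
  cat("Eco-region calls (alpha = ", attr(x, "alpha"), "):\n", sep = "")
  print(table(x$call))
  NextMethod()
}
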