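#' Design of a synthetic multi-kingdom plankton survey
#'
#' Bundles the generative parameters for [generate_community()]. The
#' defaults emulate a trans-kingdom trans-ocean survey: 25 stations of
#' which 13 overlay an oxygen minimum zone, one merged epipelagic and one
#' mesopelagic sample per station, multinomial sequencing to a fixed
#' library size, log2 fold-change 2 eco-region signatures, and three
#' planted co-occurrence modules.
#'
#' @param n_stations number of stations; each contributes one epipelagic
#'   and one mesopelagic sample (or SRF+DCM+MES with
#'   `split_epipelagic = TRUE`).
#' @param n_omz_stations stations whose mesopelagic sample sits in an OMZ.
#' @param taxa_per_group named integer vector of taxa counts per organism
#'   group.
#' @param signature_fractions named proportions of taxa planted as EPI,
#'   OXIC_MES, OMZ and CORE_MES signatures (must sum to <= 1; the
#'   remainder is ubiquitous).
#' @param effect_size_log2 log2 fold-change of a signature taxon in its
#'   home eco-region (CORE_MES taxa are elevated in both mesopelagic
#'   regions).
#' @param depth_reads multinomial library size per sample.
#' @param dispersion standard deviation of the taxon-sample log-abundance
#'   noise.
#' @param n_modules,module_taxa,module_strength planted co-occurrence
#'   modules: number, taxa per module, and loading on the shared
#'   per-sample Gaussian factor.
#' @param split_epipelagic emit separate SRF and DCM samples (each drawn
#'   from the epipelagic composition at half depth) instead of one merged
#'   EPI column.
#' @param structural_zero_rate fraction of taxon-sample cells forced to
#'   zero before sequencing (stress-test knob; default 0).
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return a `synthetic_design` list.
#' @export
synthetic_design <- function(n_stations = 25, n_omz_stations = 13,
                             taxa_per_group = c(prokaryote = 60,
                                                picoeukaryote = 60,
                                                ncldv = 40),
                             signature_fractions = c(EPI = 0.15,
                                                     OXIC_MES = 0.15,
                                                     OMZ = 0.15,
                                                     CORE_MES = 0.15),
                             effect_size_log2 = 2, depth_reads = 2e4,
                             dispersion = 0.5, n_modules = 3,
                             module_taxa = 30, module_strength = 0,
                             split_epipelagic = FALSE,
                             structural_zero_rate = 0, seed = 1) {
  if (sum(taxa_per_group) == 0 || n_stations == 0) abort("Degenerate design: no taxa or stations.")
  if (n_omz_stations > n_stations) abort("n_omz_stations cannot exceed n_stations.")
  if (sum(signature_fractions) > 1 + 1e-9) abort("signature_fractions must sum to <= 1.")
  if (dispersion <= 0) abort("dispersion must be positive.")
  if (effect_size_log2 < 0 || module_strength < 0) abort("Effect sizes must be >= 0.")
  structure(as.list(environment()), class = "synthetic_design")
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Generate a synthetic OTU table, environmental table and ground truth
#'
#' Per sample `s` with eco-region `r`, the latent log-abundance of taxon
#' `t` is
#' \deqn{\lambda_{ts} = \beta_t + \mathrm{effect} \cdot \ln 2 \cdot
#' 1[t \text{ signature of } r] + \mathrm{strength} \cdot L_{m(t)} f_{ms}
#' + \varepsilon_{ts}} with taxon baselines \eqn{\beta_t \sim N(0, 1)},
#' noise \eqn{\varepsilon \sim N(0, \sigma)}, and per-sample module
#' factors \eqn{f_{ms} \sim N(0, 1)} shared by all taxa of module `m`
#' (CORE_MES signatures count for both mesopelagic regions). Counts are
#' drawn multinomially with `depth_reads` trials from the softmax of the
#' latent column, so compositional artefacts are genuinely present and
#' zeros arise from sampling depth. Environmental variables carry planted
#' gradients: oxygen Uniform(0.5, 9) umol/kg in OMZ versus
#' Uniform(40, 250) in oxic mesopelagic (epipelagic near saturation),
#' nitrate elevated at depth, and particle flux correlated with a
#' designated taxa subset.
#'
#' @param design a [synthetic_design()].
#' @return list with `otu` (an [otu_table()] with labelled samples),
#'   `env` (tibble of per-sample environmental variables), and `truth`
#'   (tibbles `taxa` — true class and module — and `samples`, plus the
#'   latent `lambda` matrix).
#' @export
generate_community <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  d <- design
  withr::with_seed(d$seed, {
    groups <- rep(names(d$taxa_per_group), d$taxa_per_group)
    p <- length(groups)
    taxa <- sprintf("%s_%03d", groups, unlist(lapply(d$taxa_per_group, seq_len)))

    # planted eco-region classes
    classes <- rep("UBIQUITOUS", p)
    n_sig <- floor(d$signature_fractions * p)
    pos <- 1
    for (cl in names(n_sig)) {
      if (n_sig[[cl]] > 0 && pos <= p) {
        idx <- pos:min(p, pos + n_sig[[cl]] - 1)
        classes[idx] <- cl
        pos <- pos + length(idx)
      }
    }

    # planted modules over the tail of the taxa list (may overlap classes)
    module <- rep(0L, p)
    if (d$n_modules > 0 && d$module_taxa > 0) {
      need <- d$n_modules * d$module_taxa
      if (need > p) abort("Not enough taxa for the requested modules.")
      mod_idx <- (p - need + 1):p
      module[mod_idx] <- rep(seq_len(d$n_modules), each = d$module_taxa)
    }

    # stations and samples
    stations <- sprintf("st%02d", seq_len(d$n_stations))
    omz_st <- stations[seq_len(d$n_omz_stations)]
    epi_layers <- if (d$split_epipelagic) c("SRF", "DCM") else "EPI"
    sm <- purrr::map_dfr(stations, function(st) {
      bind_rows(
        tibble(sample_id = paste0(st, "_", epi_layers), station = st,
               layer = epi_layers, ecoregion = "EPI",
               o2_umol_kg = runif(length(epi_layers), 180, 250)),
        tibble(sample_id = paste0(st, "_MES"), station = st, layer = "MES",
               ecoregion = if (st %in% omz_st) "OMZ" else "OXIC_MES",
               o2_umol_kg = if (st %in% omz_st) runif(1, 0.5, 9) else runif(1, 40, 250)))
    })
    sm$basin <- rep(c("IO", "PO", "SAO", "NAO"), length.out = nrow(sm))
    n_s <- nrow(sm)

    beta <- rnorm(p, 0, 1)
    eff <- d$effect_size_log2 * log(2)
    sig_on <- function(cl, r) {
      (cl == r & r %in% c("EPI", "OXIC_MES", "OMZ")) |
        (cl == "CORE_MES" & r %in% c("OXIC_MES", "OMZ"))
    }
    f_ms <- matrix(rnorm(d$n_modules * n_s), d$n_modules, n_s)
    lambda <- matrix(0, p, n_s, dimnames = list(taxa, sm$sample_id))
    for (s in seq_len(n_s)) {
      r <- sm$ecoregion[s]
      mu <- beta + eff * sig_on(classes, r)
      if (d$n_modules > 0) {
        on <- module > 0
        mu[on] <- mu[on] + d$module_strength * f_ms[module[on], s]
      }
      lambda[, s] <- mu + rnorm(p, 0, d$dispersion)
    }
    if (d$structural_zero_rate > 0) {
      drop <- matrix(runif(p * n_s) < d$structural_zero_rate, p, n_s)
      lambda[drop] <- -Inf
    }

    counts <- matrix(0L, p, n_s, dimnames = list(taxa, sm$sample_id))
    for (s in seq_len(n_s)) {
      pr <- softmax(lambda[, s])
      counts[, s] <- rmultinom(1, d$depth_reads, pr)[, 1]
    }

    # environmental covariates with planted gradients
    mes <- sm$layer == "MES"
    flux_taxa <- which(classes == "CORE_MES")
    if (!length(flux_taxa)) flux_taxa <- seq_len(min(10, p))
    flux_signal <- colMeans(lambda[flux_taxa, , drop = FALSE])
    flux_signal[!is.finite(flux_signal)] <- min(flux_signal[is.finite(flux_signal)])
    env <- tibble(
      sample_id = sm$sample_id,
      temperature_C = ifelse(mes, runif(n_s, 4, 12), runif(n_s, 15, 28)),
      salinity_PSU = rnorm(n_s, 35, 0.4),
      o2_umol_kg = sm$o2_umol_kg,
      no3_umol_L = ifelse(mes, rnorm(n_s, 25, 4), abs(rnorm(n_s, 4, 2))),
      chla_umol_m3 = ifelse(mes, abs(rnorm(n_s, 0.02, 0.01)),
                            abs(rnorm(n_s, 0.4, 0.15))),
      particle_flux = as.numeric(scale(flux_signal)) + rnorm(n_s, 0, 0.5))

    otu <- otu_table(counts,
                     taxon_meta = tibble(taxon_id = taxa, group = groups),
                     sample_meta = sm)
    truth <- list(
      taxa = tibble(taxon_id = taxa, group = groups, class = classes,
                    module = module),
      samples = sm[, c("sample_id", "station", "layer", "ecoregion")],
      lambda = lambda)
    list(otu = otu, env = env, truth = truth)
  })
}

#' Write a named synthetic fixture as TSV files
#'
#' Catalogue: `"tiny"` (10 taxa x 6 samples, hand-checkable), `"null"`
#' (no planted structure: effect 0, no modules), `"omz_demo"` (three
#' eco-regions with planted log2FC 2 signatures and three planted
#' modules).
#'
#' @param name one of `"tiny"`, `"null"`, `"omz_demo"`.
#' @param dir output directory (created if needed).
#' @param seed RNG seed forwarded to the design.
#' @return invisibly, the named list of file paths written (`counts`,
#'   `taxon_meta`, `sample_meta`, `env`, `truth`).
#' @export
make_fixture <- function(name, dir = ".", seed = 1) {
  designs <- list(
    tiny = synthetic_design(n_stations = 3, n_omz_stations = 1,
                            taxa_per_group = c(prokaryote = 6, ncldv = 4),
                            depth_reads = 500, n_modules = 0, module_taxa = 0,
                            seed = seed),
    null = synthetic_design(n_stations = 12, n_omz_stations = 6,
                            taxa_per_group = c(prokaryote = 20,
                                               picoeukaryote = 10),
                            effect_size_log2 = 0, module_strength = 0,
                            n_modules = 0, module_taxa = 0,
                            signature_fractions = c(EPI = 0, OXIC_MES = 0,
                                                    OMZ = 0, CORE_MES = 0),
                            depth_reads = 5000, seed = seed),
    omz_demo = synthetic_design(n_stations = 16, n_omz_stations = 8,
                                module_strength = 3, seed = seed))
  if (!name %in% names(designs)) {
    abort(paste0("Unknown fixture '", name, "'. Catalogue: ",
                 paste(names(designs), collapse = ", ")))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- generate_community(designs[[name]])
  paths <- list(
    counts = file.path(dir, paste0(name, "_counts.tsv")),
    taxon_meta = file.path(dir, paste0(name, "_taxa.tsv")),
    sample_meta = file.path(dir, paste0(name, "_samples.tsv")),
    env = file.path(dir, paste0(name, "_env.tsv")),
    truth = file.path(dir, paste0(name, "_truth.tsv")))
  write_otu_table(sim$otu, paths$counts, paths$taxon_meta, paths$sample_meta)
  readr::write_tsv(sim$env, paths$env)
  readr::write_tsv(sim$truth$taxa, paths$truth)
  invisible(paths)
}
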