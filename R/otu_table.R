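#' OTU count table with taxon and sample metadata
#'
#' `otu_table()` bundles a taxa-by-samples matrix of non-negative integer
#' read counts with a per-taxon metadata tibble (organism group, taxonomy)
#' and a per-sample metadata tibble (station, depth layer, basin, water
#' mass, oxygen concentration, eco-region label). All pipeline verbs take
#' this container as their first argument and return it (or a tibble), so
#' calls chain with the pipe.
#'
#' @param counts numeric matrix, taxa in rows and samples in columns, with
#'   unique rownames (taxon ids) and colnames (sample ids). Values must be
#'   non-negative whole numbers.
#' @param taxon_meta data frame with at least a `taxon_id` column; optional
#'   `group` (one of `"phage"`, `"ncldv"`, `"prokaryote"`, `"picoeukaryote"`)
#'   and `taxonomy` columns. Missing taxa are filled with `NA`.
#' @param sample_meta data frame with at least `sample_id`, `station` and
#'   `layer` (`"SRF"`, `"DCM"`, `"MES"`, or `"EPI"` for merged epipelagic
#'   columns); optional `basin`, `water_mass`, `o2_umol_kg`, `ecoregion`.
#'
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `taxon_meta` and `sample_meta`.
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 1L, 3L, 4L), nrow = 3,
#'             dimnames = list(paste0("t", 1:3), c("s1", "s2")))
#' ot <- otu_table(m,
#'   taxon_meta  = tibble::tibble(taxon_id = paste0("t", 1:3), group = "prokaryote"),
#'   sample_meta = tibble::tibble(sample_id = c("s1", "s2"),
#'                                station = c("100", "100"),
#'                                layer = c("SRF", "MES")))
#' ot
otu_table <- function(counts, taxon_meta = NULL, sample_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have rownames (taxon ids) and colnames (sample ids).")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    abort(paste0("Duplicate taxon ids: ", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(colnames(counts))) {
    abort("Duplicate sample ids in `counts` columns.")
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    abort("`counts` must be numeric with no missing values.")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must contain non-negative integers (read counts).")
  }
  storage.mode(counts) <- "integer"

  if (is.null(taxon_meta)) {
    taxon_meta <- tibble(taxon_id = rownames(counts))
  }
  taxon_meta <- as_tibble(taxon_meta)
  if (!"taxon_id" %in% names(taxon_meta)) abort("`taxon_meta` needs a `taxon_id` column.")
  unknown_taxa <- setdiff(taxon_meta$taxon_id, rownames(counts))
  if (length(unknown_taxa)) {
    warn(paste0("taxon_meta ids not in count matrix (dropped): ",
                paste(utils::head(unknown_taxa, 5), collapse = ", ")))
  }
  taxon_meta <- left_join(tibble(taxon_id = rownames(counts)), taxon_meta,
                          by = "taxon_id")
  if (!"group" %in% names(taxon_meta)) taxon_meta$group <- NA_character_
  if (!"taxonomy" %in% names(taxon_meta)) taxon_meta$taxonomy <- NA_character_

  if (is.null(sample_meta)) {
    sample_meta <- tibble(sample_id = colnames(counts),
                          station = NA_character_, layer = NA_character_)
  }
  sample_meta <- as_tibble(sample_meta)
  if (!"sample_id" %in% names(sample_meta)) abort("`sample_meta` needs a `sample_id` column.")
  unknown_samples <- setdiff(sample_meta$sample_id, colnames(counts))
  if (length(unknown_samples)) {
    warn(paste0("sample_meta ids not in count matrix (dropped): ",
                paste(utils::head(unknown_samples, 5), collapse = ", ")))
  }
  sample_meta <- left_join(tibble(sample_id = colnames(counts)), sample_meta,
                           by = "sample_id")
  for (col in c("station", "layer", "basin", "water_mass", "ecoregion")) {
    if (!col %in% names(sample_meta)) sample_meta[[col]] <- NA_character_
    sample_meta[[col]] <- as.character(sample_meta[[col]])
  }
  if (!"o2_umol_kg" %in% names(sample_meta)) sample_meta$o2_umol_kg <- NA_real_
  bad_layer <- !is.na(sample_meta$layer) &
    !sample_meta$layer %in% c("SRF", "DCM", "MES", "EPI")
  if (any(bad_layer)) {
    abort(paste0("Invalid layer values: ",
                 paste(unique(sample_meta$layer[bad_layer]), collapse = ", "),
                 " (expected SRF, DCM, MES or EPI)."))
  }
  if (any(!is.na(sample_meta$o2_umol_kg) & sample_meta$o2_umol_kg < 0)) {
    abort("`o2_umol_kg` must be non-negative.")
  }

  structure(list(counts = counts, taxon_meta = taxon_meta,
                 sample_meta = sample_meta),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("<otu_table> ", nrow(x$counts), " taxa x ", ncol(x$counts), " samples\n",
      sep = "")
  grp <- table(x$taxon_meta$group, useNA = "ifany")
  cat("  groups: ", paste(names(grp), grp, sep = ":", collapse = "  "), "\n")
  lay <- table(x$sample_meta$layer, useNA = "ifany")
  cat("  layers: ", paste(names(lay), lay, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Number of taxa / samples in an `otu_table`
#' @param table an [otu_table()].
#' @return integer scalar.
#' @export
n_taxa <- function(table) nrow(table$counts)

#' @rdname n_taxa
#' @export
n_samples <- function(table) ncol(table$counts)

#' @export
as_tibble.otu_table <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "taxon_id") |>
    tidyr::pivot_longer(-"taxon_id", names_to = "sample_id",
                        values_to = "count")
  long |>
    left_join(x$taxon_meta, by = "taxon_id") |>
    left_join(x$sample_meta, by = "sample_id")
}

delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read / write an OTU table and its metadata from delimited files
#'
#' The count file is a TSV or CSV with taxa as rows (first column = taxon
#' id) and samples as columns. Metadata files are keyed by `taxon_id` /
#' `sample_id` header columns. Delimiter is inferred from the file
#' extension (`.csv` = comma, otherwise tab).
#'
#' @param path count matrix file.
#' @param taxon_meta_path,sample_meta_path optional metadata files.
#' @return [read_otu_table()] returns a validated [otu_table()];
#'   [write_otu_table()] returns `path` invisibly.
#' @export
read_otu_table <- function(path, taxon_meta_path = NULL, sample_meta_path = NULL) {
  counts_df <- readr::read_delim(path, delim = delim_for(path),
                                 show_col_types = FALSE, progress = FALSE)
  ids <- as.character(counts_df[[1]])
  m <- as.matrix(counts_df[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("Count columns must be numeric.")
  rownames(m) <- ids
  taxon_meta <- if (!is.null(taxon_meta_path)) {
    readr::read_delim(taxon_meta_path, delim = delim_for(taxon_meta_path),
                      show_col_types = FALSE, progress = FALSE)
  }
  sample_meta <- if (!is.null(sample_meta_path)) {
    readr::read_delim(sample_meta_path, delim = delim_for(sample_meta_path),
                      show_col_types = FALSE, progress = FALSE)
  }
  otu_table(m, taxon_meta = taxon_meta, sample_meta = sample_meta)
}

#' @rdname read_otu_table
#' @param table an [otu_table()] to write.
#' @export
write_otu_table <- function(table, path, taxon_meta_path = NULL,
                            sample_meta_path = NULL) {
  stopifnot(inherits(table, "otu_table"))
  out <- as_tibble(table$counts, rownames = "taxon_id")
  readr::write_delim(out, path, delim = delim_for(path))
  if (!is.null(taxon_meta_path)) {
    readr::write_delim(table$taxon_meta, taxon_meta_path,
                       delim = delim_for(taxon_meta_path))
  }
  if (!is.null(sample_meta_path)) {
    readr::write_delim(table$sample_meta, sample_meta_path,
                       delim = delim_for(sample_meta_path))
  }
  invisible(path)
}

#' Label samples with their eco-region from depth layer and oxygen
#'
#' Epipelagic samples (`SRF`, `DCM`, or merged `EPI`) are labelled `EPI`.
#' Mesopelagic samples are labelled `OMZ` when the oxygen concentration at
#' the sampled depth falls below the suboxic threshold (10 umol O2/kg by
#' convention), and `OXIC_MES` otherwise; samples below the anoxic
#' threshold (0.003 umol/kg, the detection limit of the most sensitive
#' sensors) additionally get an `anoxic` flag.
#'
#' @param table an [otu_table()] whose MES samples carry `o2_umol_kg`.
#' @param suboxic_threshold,anoxic_threshold oxygen cut-offs in umol/kg.
#' @param overwrite replace existing `ecoregion` labels? Default keeps them.
#' @return the table with `ecoregion` (and logical `anoxic`) columns filled
#'   in `sample_meta`. Idempotent.
#' @export
label_sample_ecoregions <- function(table, suboxic_threshold = 10,
                                    anoxic_threshold = 0.003,
                                    overwrite = FALSE) {
  stopifnot(inherits(table, "otu_table"))
  sm <- table$sample_meta
  if (!"anoxic" %in% names(sm)) sm$anoxic <- NA
  todo <- if (overwrite) rep(TRUE, nrow(sm)) else is.na(sm$ecoregion)

  mes <- sm$layer == "MES"
  missing_o2 <- todo & mes & is.na(sm$o2_umol_kg)
  if (any(missing_o2)) {
    abort(paste0("MES samples without o2_umol_kg and no prior eco-region: ",
                 paste(sm$sample_id[missing_o2], collapse = ", ")))
  }
  epi <- todo & sm$layer %in% c("SRF", "DCM", "EPI")
  sm$ecoregion[epi] <- "EPI"
  omz <- todo & mes & sm$o2_umol_kg < suboxic_threshold
  sm$ecoregion[omz] <- "OMZ"
  sm$anoxic[todo & mes] <- sm$o2_umol_kg[todo & mes] < anoxic_threshold
  sm$ecoregion[todo & mes & !omz] <- "OXIC_MES"

  table$sample_meta <- sm
  table
}

#' Merge surface and DCM samples into one epipelagic column per station
#'
#' For each station, the surface (`SRF`) and deep-chlorophyll-maximum
#' (`DCM`) columns are replaced by a single merged epipelagic column named
#' `"<station>_EPI"` whose count for every taxon is the sum of the layer
#' counts; taxa observed in only one of the two layers keep their counts
#' unchanged. Mesopelagic columns are untouched, so total reads per
#' station are conserved. The ids of the merged source columns are kept in
#' a `merged_from` metadata column.
#'
#' @param table an [otu_table()] containing SRF and/or DCM samples.
#' @return an [otu_table()] with merged EPI columns (stations with neither
#'   epipelagic layer are passed through with a message).
#' @export
merge_epipelagic <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  sm <- table$sample_meta
  epi_idx <- which(sm$layer %in% c("SRF", "DCM"))
  if (!length(epi_idx)) {
    inform("No SRF/DCM samples; nothing to merge.")
    return(table)
  }
  stations <- unique(sm$station)
  no_epi <- setdiff(stations, sm$station[epi_idx])
  if (length(no_epi)) {
    inform(paste0("Stations without SRF/DCM (left as is): ",
                  paste(no_epi, collapse = ", ")))
  }

  merged_cols <- list()
  merged_meta <- list()
  for (st in unique(sm$station[epi_idx])) {
    cols <- which(sm$station == st & sm$layer %in% c("SRF", "DCM"))
    merged_cols[[st]] <- as.integer(rowSums(table$counts[, cols, drop = FALSE]))
    src <- sm[cols, ]
    merged_meta[[st]] <- tibble(
      sample_id = paste0(st, "_EPI"), station = st, layer = "EPI",
      basin = src$basin[which(!is.na(src$basin))[1] %||% 1],
      water_mass = NA_character_, o2_umol_kg = NA_real_,
      ecoregion = "EPI",
      merged_from = paste(src$sample_id, collapse = "+"))
  }
  epi_counts <- do.call(cbind, merged_cols)
  colnames(epi_counts) <- paste0(names(merged_cols), "_EPI")
  keep <- setdiff(seq_len(ncol(table$counts)), epi_idx)
  new_counts <- cbind(epi_counts, table$counts[, keep, drop = FALSE])
  keep_meta <- sm[keep, ]
  if (!"merged_from" %in% names(keep_meta)) keep_meta$merged_from <- NA_character_
  new_meta <- bind_rows(bind_rows(merged_meta), keep_meta)
  extra <- setdiff(names(sm), names(new_meta))
  for (col in extra) new_meta[[col]] <- NA

  out <- table
  out$counts <- new_counts
  out$sample_meta <- new_meta[match(colnames(new_counts), new_meta$sample_id), ]
  out
}

#' Discard rare and sparse taxa
#'
#' A taxon is discarded only when it is both rare (dataset-wide relative
#' abundance, taxon total over grand total, below `min_rel_abundance`) and
#' sparse (observed with a positive count in fewer than `min_observations`
#' samples). The conjunction keeps abundant-but-localised taxa such as OMZ
#' specialists. The ids of removed taxa are attached as the
#' `"removed_taxa"` attribute.
#'
#' @param table an [otu_table()].
#' @param min_rel_abundance dataset-wide relative-abundance floor
#'   (default `1e-4`).
#' @param min_observations prevalence floor in number of samples
#'   (default 5).
#' @return the filtered [otu_table()]; errors if every taxon would be
#'   removed.
#' @export
filter_otus <- function(table, min_rel_abundance = 1e-4, min_observations = 5) {
  stopifnot(inherits(table, "otu_table"))
  if (!length(table$counts)) abort("Empty count matrix.")
  totals <- rowSums(table$counts)
  rel <- totals / sum(totals)
  prev <- rowSums(table$counts > 0)
  drop <- rel < min_rel_abundance & prev < min_observations
  if (all(drop)) {
    abort("All taxa removed by the abundance/prevalence filter; review thresholds.")
  }
  removed <- rownames(table$counts)[drop]
  out <- table
  out$counts <- table$counts[!drop, , drop = FALSE]
  out$taxon_meta <- table$taxon_meta[!drop, ]
  attr(out, "removed_taxa") <- removed
  out
}
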