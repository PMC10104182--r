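#' Build the synthetic cortical parcellation
#'
#' Partitions the simulated sources into labelled regions with hemisphere and
#' lobe metadata, a homologous left/right pair registry, a set of unpaired
#' (asymmetric) regions, and temporal-lobe flags. Defaults give 114 regions:
#' 54 homologous pairs plus 6 unpaired midline regions, with 13 pairs
#' (26 regions) labelled temporal.
#'
#' @param config a [sim_config()].
#' @return an object of class `parcellation`: `$roi` (region table),
#'   `$source_roi` (region id per source), `$n_rois`, `$pairs` (pair table).
#' @examples
#' p <- make_parcellation(sim_config())
#' nrow(p$roi)          # 114
#' sum(p$roi$temporal)  # 26
#' @export
make_parcellation <- function(config) {
  validate_sim_config(config)
  g <- source_geometry(config)
  pairs <- unique(g$roi$pair_id[!is.na(g$roi$pair_id)])
  pair_tab <- do.call(rbind, lapply(pairs, function(p) {
    sub <- g$roi[!is.na(g$roi$pair_id) & g$roi$pair_id == p, ]
    data.frame(pair_id = p,
               roi_left = sub$roi_id[sub$hemisphere == "L"],
               roi_right = sub$roi_id[sub$hemisphere == "R"],
               temporal = sub$temporal[1],
               anteriority = sub$cy[1])
  }))
  structure(list(roi = g$roi, source_roi = g$source_roi,
                 n_rois = nrow(g$roi), pairs = pair_tab),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d ROIs: %d pairs (%d temporal), %d unpaired; %d sources\n",
              x$n_rois, nrow(x$pairs), sum(x$pairs$temporal),
              sum(x$roi$hemisphere == "M"), length(x$source_roi)))
  invisible(x)
}

#' Sources belonging to one region
#' @param parcellation a [make_parcellation()] result.
#' @param roi_id region id.
#' @return integer source indices.
#' @export
roi_sources <- function(parcellation, roi_id) which(parcellation$source_roi == roi_id)

#' Temporal-lobe homologous pairs ordered by anteriority
#'
#' Most-anterior first; the leading pairs stand in for the anterior temporal
#' structures (entorhinal-like) where the planted patient abnormality sits.
#'
#' @param parcellation a parcellation.
#' @return the `$pairs` rows with `temporal == TRUE`, most anterior first.
#' @export
temporal_pairs <- function(parcellation) {
  tp <- parcellation$pairs[parcellation$pairs$temporal, , drop = FALSE]
  tp[order(-tp$anteriority), , drop = FALSE]
}

#' Default planted band-power topography
#'
#' Smooth positive weights per region and band encoding the expected healthy
#' topography: alpha strongest over posterior regions, delta strongest over
#' anterior temporal and frontal regions, theta mildly frontal-midline, beta
#' mildly central, gamma low and flat. Rows are normalised to sum to 1.
#' The map is left/right symmetric by construction (it depends on |x|, y, z
#' only), so homologous regions receive identical planted profiles.
#'
#' @param parcellation a parcellation.
#' @param scheme a [band_scheme()].
#' @return ROIs x bands matrix, rows summing to 1.
#' @export
default_band_profiles <- function(parcellation, scheme = band_scheme()) {
  r <- parcellation$roi
  sig <- function(x) 1 / (1 + exp(-x))
  w <- cbind(
    delta = 0.20 + 0.45 * sig(3 * r$cy) + 0.25 * r$temporal,
    theta = 0.18 + 0.20 * sig(2 * r$cy) * (1 - abs(r$cx)),
    alpha = 0.30 + 0.55 * sig(-3 * r$cy),
    beta  = 0.16 + 0.15 * exp(-r$cy^2 / 0.2),
    gamma = 0.07 + 0.06 * exp(-(r$cy - 0.1)^2 / 0.15)
  )
  w <- w[, band_names(scheme)[band_names(scheme) %in% colnames(w)], drop = FALSE]
  if (ncol(w) != n_bands(scheme))
    stop_named("default profiles only cover the five classical bands; supply band_profiles for custom schemes")
  w <- w / rowSums(w)
  rownames(w) <- r$roi_name
  w
}

#' Write / read a parcellation as TSV
#'
#' One row per region: roi_id, roi_name, hemisphere, lobe, pair_id, temporal,
#' and the space-separated source ids of the region.
#'
#' @param parcellation a parcellation.
#' @param path output TSV path.
#' @return `path` invisibly (`write_parcellation`); a `parcellation`
#'   (`read_parcellation`).
#' @export
write_parcellation <- function(parcellation, path) {
  tab <- parcellation$roi[, c("roi_id", "roi_name", "hemisphere", "lobe",
                              "pair_id", "temporal", "cx", "cy", "cz")]
  tab$source_ids <- vapply(parcellation$roi$roi_id, function(id)
    paste(roi_sources(parcellation, id), collapse = " "), "")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  src <- lapply(strsplit(tab$source_ids, " "), as.integer)
  n_src <- max(unlist(src))
  source_roi <- integer(n_src)
  for (i in seq_len(nrow(tab))) source_roi[src[[i]]] <- tab$roi_id[i]
  roi <- tab[, c("roi_id", "roi_name", "hemisphere", "lobe", "pair_id",
                 "temporal", "cx", "cy", "cz")]
  pairs <- unique(roi$pair_id[!is.na(roi$pair_id)])
  pair_tab <- do.call(rbind, lapply(pairs, function(p) {
    sub <- roi[!is.na(roi$pair_id) & roi$pair_id == p, ]
    data.frame(pair_id = p,
               roi_left = sub$roi_id[sub$hemisphere == "L"],
               roi_right = sub$roi_id[sub$hemisphere == "R"],
               temporal = sub$temporal[1], anteriority = sub$cy[1])
  }))
  structure(list(roi = roi, source_roi = source_roi, n_rois = nrow(roi),
                 pairs = pair_tab), class = "parcellation")
}
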