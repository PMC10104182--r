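#' Spearman rank correlation
#'
#' Pearson correlation of average-tied ranks. Errors explicitly on constant
#' input rather than returning NA, since a constant map would silently void
#' a robustness claim.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_named("x and y differ in length")
  if (length(x) < 3) stop_named("need >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_named("Spearman correlation undefined for a constant vector")
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

#' Build a normative map from a healthy cohort
#'
#' Elementwise mean and sample SD (denominator n-1) of the subjects'
#' relative band-power maps: the `mu_ij` / `sigma_ij` reference against which
#' patients are z-scored.
#'
#' @param maps list of [relative_band_power()] maps (or bare ROIs x bands
#'   matrices) with identical ROI/band axes.
#' @param provenance free-text description (epoch, pipeline settings).
#' @return object of class `normative_map`: `$mu`, `$sigma` (ROIs x bands),
#'   `$n_subjects`, `$provenance`.
#' @export
build_normative_map <- function(maps, provenance = "") {
  vals <- lapply(maps, function(m) if (inherits(m, "band_power_map")) m$values else m)
  if (length(vals) < 2) stop_named("need >= 2 subjects")
  ref <- dim(vals[[1]])
  for (i in seq_along(vals)) {
    if (!all(dim(vals[[i]]) == ref))
      stop_named("subject %d has a %dx%d map; expected %dx%d", i,
                 nrow(vals[[i]]), ncol(vals[[i]]), ref[1], ref[2])
    if (!is.null(dimnames(vals[[1]])) && !is.null(dimnames(vals[[i]])) &&
        !identical(dimnames(vals[[i]]), dimnames(vals[[1]])))
      stop_named("subject %d has inconsistent ROI/band labels", i)
  }
  arr <- simplify2array(vals)
  mu <- apply(arr, c(1, 2), mean)
  sigma <- apply(arr, c(1, 2), stats::sd)
  structure(list(mu = mu, sigma = sigma, n_subjects = length(vals),
                 provenance = provenance),
            class = "normative_map")
}

#' @export
print.normative_map <- function(x, ...) {
  cat(sprintf("<normative_map> %d ROIs x %d bands from %d subjects\n",
              nrow(x$mu), ncol(x$mu), x$n_subjects))
  if (nzchar(x$provenance)) cat(" ", x$provenance, "\n")
  invisible(x)
}

#' Robustness of the normative map to epoch choice
#'
#' Builds one normative map per non-overlapping epoch and reports the
#' Spearman correlation between epoch-wise maps on the pooled ROI x band
#' vector (each region represented once per band), separately for the means
#' and the SDs.
#'
#' @param ts_list list of `roi_timeseries`, one per healthy subject.
#' @param scheme a [band_scheme()].
#' @param epoch_duration epoch length, seconds (default 30).
#' @param n_epochs number of non-overlapping epochs (default 3).
#' @param window,overlap Welch parameters.
#' @return object of class `robustness_report`: `$rho_mean`, `$rho_sd`
#'   (mean pairwise rho), `$pairwise` (per-pair table), `$n_epochs`.
#' @export
epoch_robustness <- function(ts_list, scheme = band_scheme(),
                             epoch_duration = 30, n_epochs = 3,
                             window = 2, overlap = 0.5) {
  total <- min(vapply(ts_list, function(t) ncol(t$data) / t$fs, 0))
  starts <- epoch_plan(total, epoch_duration, n_epochs)
  norms <- lapply(starts, function(s0) {
    maps <- lapply(seq_along(ts_list), function(i)
      bandpower_map(ts_list[[i]], scheme, epoch_start = s0,
                    epoch_duration = epoch_duration, window = window,
                    overlap = overlap, subject_id = as.character(i)))
    build_normative_map(maps, provenance = sprintf("epoch %g-%g s", s0,
                                                   s0 + epoch_duration))
  })
  pairs <- utils::combn(length(norms), 2)
  tab <- data.frame(epoch_a = pairs[1, ], epoch_b = pairs[2, ],
                    rho_mean = NA_real_, rho_sd = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    a <- norms[[pairs[1, i]]]; b <- norms[[pairs[2, i]]]
    tab$rho_mean[i] <- spearman_rho(as.vector(a$mu), as.vector(b$mu))
    tab$rho_sd[i] <- spearman_rho(as.vector(a$sigma), as.vector(b$sigma))
  }
  structure(list(rho_mean = mean(tab$rho_mean), rho_sd = mean(tab$rho_sd),
                 pairwise = tab, n_epochs = n_epochs, maps = norms),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("<robustness_report> %d epochs: mean rho(mu) = %.3f, rho(sigma) = %.3f\n",
              x$n_epochs, x$rho_mean, x$rho_sd))
  invisible(x)
}

#' Left-right symmetry of a normative map
#'
#' Spearman correlation of left vs right homologous-region mean relative
#' band power, pooled across bands (each pair contributes one point per
#' band). Regions without a homologue are excluded and reported.
#'
#' @param map a [build_normative_map()] result.
#' @param parcellation a [make_parcellation()] result.
#' @return object of class `symmetry_report`: `$rho_lr`, `$n_pairs_used`,
#'   `$excluded_rois`.
#' @export
lr_symmetry <- function(map, parcellation) {
  pr <- parcellation$pairs
  if (nrow(pr) < 2) stop_named("need >= 2 homologous pairs")
  left <- map$mu[pr$roi_left, , drop = FALSE]
  right <- map$mu[pr$roi_right, , drop = FALSE]
  excluded <- parcellation$roi$roi_name[is.na(parcellation$roi$pair_id)]
  structure(list(rho_lr = spearman_rho(as.vector(left), as.vector(right)),
                 n_pairs_used = nrow(pr), excluded_rois = excluded),
            class = "symmetry_report")
}

#' @export
print.symmetry_report <- function(x, ...) {
  cat(sprintf("<symmetry_report> rho(L,R) = %.3f over %d pairs (%d unpaired regions excluded)\n",
              x$rho_lr, x$n_pairs_used, length(x$excluded_rois)))
  invisible(x)
}

#' Cross-modality comparison of two normative maps
#'
#' Per-band Spearman correlation of the mean maps over the regions shared by
#' both maps (matched by row name); regions present in only one map are
#' dropped pairwise and reported.
#'
#' @param map_a,map_b [build_normative_map()] results (e.g., scalp EEG vs
#'   MEG- or iEEG-derived maps).
#' @param labels modality labels, length 2.
#' @return object of class `crossmodal_report`: `$rho` (named per band),
#'   `$n_shared`, `$dropped`, `$labels`.
#' @export
cross_modal_correlation <- function(map_a, map_b,
                                    labels = c("modality_a", "modality_b")) {
  ra <- rownames(map_a$mu) %||% as.character(seq_len(nrow(map_a$mu)))
  rb <- rownames(map_b$mu) %||% as.character(seq_len(nrow(map_b$mu)))
  shared <- intersect(ra, rb)
  if (length(shared) < 3) stop_named("need >= 3 shared ROIs (have %d)",
                                     length(shared))
  a <- map_a$mu[match(shared, ra), , drop = FALSE]
  b <- map_b$mu[match(shared, rb), , drop = FALSE]
  if (ncol(a) != ncol(b)) stop_named("maps have different band counts")
  rho <- vapply(seq_len(ncol(a)), function(j) spearman_rho(a[, j], b[, j]), 0)
  names(rho) <- colnames(map_a$mu)
  structure(list(rho = rho, n_shared = length(shared),
                 dropped = union(setdiff(ra, shared), setdiff(rb, shared)),
                 labels = labels),
            class = "crossmodal_report")
}

#' @export
print.crossmodal_report <- function(x, ...) {
  cat(sprintf("<crossmodal_report> %s vs %s over %d shared ROIs\n",
              x$labels[1], x$labels[2], x$n_shared))
  print(round(x$rho, 3))
  invisible(x)
}

#' Write / read a normative map as TSV
#'
#' Long format: one row per region x band with columns
#' `roi`, `band`, `mean`, `sd`, `n`.
#'
#' @param map a `normative_map`.
#' @param path TSV path.
#' @return `path` invisibly; `read_normative_map` returns a `normative_map`.
#' @export
write_normative_map <- function(map, path) {
  rois <- rownames(map$mu) %||% as.character(seq_len(nrow(map$mu)))
  bands <- colnames(map$mu) %||% as.character(seq_len(ncol(map$mu)))
  tab <- data.frame(roi = rep(rois, times = length(bands)),
                    band = rep(bands, each = length(rois)),
                    mean = as.vector(map$mu), sd = as.vector(map$sigma),
                    n = map$n_subjects)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_normative_map
#' @export
read_normative_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  rois <- unique(tab$roi); bands <- unique(tab$band)
  mu <- matrix(tab$mean, nrow = length(rois), dimnames = list(rois, bands))
  sigma <- matrix(tab$sd, nrow = length(rois), dimnames = list(rois, bands))
  structure(list(mu = mu, sigma = sigma, n_subjects = tab$n[1],
                 provenance = sprintf("read from %s", path)),
            class = "normative_map")
}
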