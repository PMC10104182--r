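#' Z-score a patient map against the normative map
#'
#' `z_ij = (x_ij - mu_ij) / sigma_ij` per region and band, plus the per-ROI
#' maximum of `|z|` across bands ("maximum abnormality" indicator — no prior
#' band hypothesis). A zero normative SD anywhere is an error naming the
#' offending cells, never a silent infinity.
#'
#' @param patient a [relative_band_power()] map (or bare matrix).
#' @param norm a [build_normative_map()] result.
#' @return object of class `abnormality_map`: `$z` (ROIs x bands),
#'   `$max_abs_z` (per ROI), `$patient_id`.
#' @export
zscore_map <- function(patient, norm) {
  x <- if (inherits(patient, "band_power_map")) patient$values else patient
  pid <- if (inherits(patient, "band_power_map")) patient$subject_id else "patient"
  if (!all(dim(x) == dim(norm$mu)))
    stop_named("patient map is %dx%d but normative map is %dx%d",
               nrow(x), ncol(x), nrow(norm$mu), ncol(norm$mu))
  if (any(norm$sigma <= 0)) {
    bad <- which(norm$sigma <= 0, arr.ind = TRUE)[1, ]
    stop_named("normative SD is zero at ROI '%s', band '%s'",
               (rownames(norm$sigma) %||% seq_len(nrow(norm$sigma)))[bad[1]],
               (colnames(norm$sigma) %||% seq_len(ncol(norm$sigma)))[bad[2]])
  }
  z <- (x - norm$mu) / norm$sigma
  structure(list(z = z, max_abs_z = apply(abs(z), 1, max), patient_id = pid),
            class = "abnormality_map")
}

#' @export
print.abnormality_map <- function(x, ...) {
  cat(sprintf("<abnormality_map> '%s': %d ROIs x %d bands, max |z| = %.2f\n",
              x$patient_id, nrow(x$z), ncol(x$z), max(x$max_abs_z)))
  invisible(x)
}

#' Restrict an abnormality map to the temporal lobe
#'
#' Keeps only temporal-lobe regions (default parcellation: 26 regions =
#' 13 homologous pairs), the region set over which lateralisation is
#' assessed.
#'
#' @param map an [zscore_map()] result whose rows follow the parcellation.
#' @param parcellation a [make_parcellation()] result.
#' @return the restricted `abnormality_map`.
#' @export
restrict_temporal <- function(map, parcellation) {
  keep <- which(parcellation$roi$temporal)
  if (!length(keep)) stop_named("parcellation has no temporal ROIs")
  map$z <- map$z[keep, , drop = FALSE]
  map$max_abs_z <- map$max_abs_z[keep]
  map$roi_ids <- parcellation$roi$roi_id[keep]
  map
}

#' Lateralise cohort abnormality over homologous temporal pairs
#'
#' For each temporal pair and patient, `ipsi` is the abnormality indicator
#' (max |z| across bands) of the region on the clinically determined
#' epileptogenic side and `contra` its homologue. Per pair, the paired
#' differences `d_p = ipsi_p - contra_p` give the effect size
#' `d_z = mean(d)/sd(d)` (sample SD) and `t = d_z * sqrt(n)`. Positive
#' values mean abnormality is greater ipsilateral to the epileptogenic
#' cortex.
#'
#' @param cohort list of (full-parcellation) [zscore_map()] results, one per
#'   patient.
#' @param sides character vector of epileptogenic sides, "L" or "R".
#' @param parcellation a [make_parcellation()] result.
#' @return object of class `lateralization_result`: data.frame `$table` with
#'   one row per temporal pair (`pair_id`, `mean_ipsi`, `mean_contra`,
#'   `mean_diff`, `sd_diff`, `d_z`, `t`, `p`, `n`), plus `$n_patients`.
#'   Zero-variance differences yield `NA` effect sizes (flagged), not
#'   infinities.
#' @export
lateralize <- function(cohort, sides, parcellation) {
  if (length(cohort) < 2) stop_named("need >= 2 patients")
  if (length(sides) != length(cohort))
    stop_named("sides length (%d) != number of patients (%d)",
               length(sides), length(cohort))
  if (!all(sides %in% c("L", "R")))
    stop_named("sides must be 'L' or 'R'")
  tp <- parcellation$pairs[parcellation$pairs$temporal, , drop = FALSE]
  if (!nrow(tp)) stop_named("parcellation has no temporal pairs")
  n <- length(cohort)
  rows <- lapply(seq_len(nrow(tp)), function(k) {
    ipsi <- contra <- numeric(n)
    for (p in seq_len(n)) {
      az <- cohort[[p]]$max_abs_z
      il <- if (sides[p] == "L") tp$roi_left[k] else tp$roi_right[k]
      cl <- if (sides[p] == "L") tp$roi_right[k] else tp$roi_left[k]
      ipsi[p] <- az[il]; contra[p] <- az[cl]
    }
    d <- ipsi - contra
    sdd <- stats::sd(d)
    dz <- if (sdd > 0) mean(d) / sdd else NA_real_
    tt <- if (is.na(dz)) NA_real_ else dz * sqrt(n)
    data.frame(pair_id = tp$pair_id[k],
               roi_left = tp$roi_left[k], roi_right = tp$roi_right[k],
               mean_ipsi = mean(ipsi), mean_contra = mean(contra),
               mean_diff = mean(d), sd_diff = sdd, d_z = dz, t = tt,
               p = if (is.na(tt)) NA_real_ else
                 2 * stats::pt(-abs(tt), df = n - 1),
               n = n)
  })
  structure(list(table = do.call(rbind, rows), n_patients = n),
            class = "lateralization_result")
}

#' @export
print.lateralization_result <- function(x, ...) {
  cat(sprintf("<lateralization_result> %d temporal pairs, %d patients\n",
              nrow(x$table), x$n_patients))
  top <- x$table[order(-x$table$d_z), c("pair_id", "mean_ipsi", "mean_contra",
                                        "d_z", "t")]
  print(utils::head(top, 5), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Cohort description statistics
#'
#' Group comparison of the kind reported in a cohort table: age by
#' two-sample pooled-variance t-test computed from summary statistics, sex
#' by Pearson chi-square on the 2x2 table without continuity correction.
#'
#' @param controls,patients lists with `n`, `age_mean`, `age_sd`, `sex_m`,
#'   `sex_f`; `patients` may also carry `lat_l`, `lat_r`.
#' @return object of class `cohort_table` with `$age` (t, df, p, pooled_sd)
#'   and `$sex` (chisq, df, p, table).
#' @export
cohort_stats <- function(controls, patients) {
  for (g in list(controls, patients))
    if (g$n < 1) stop_named("empty group")
  n1 <- controls$n; n2 <- patients$n
  sp2 <- ((n1 - 1) * controls$age_sd^2 + (n2 - 1) * patients$age_sd^2) /
    (n1 + n2 - 2)
  tt <- (controls$age_mean - patients$age_mean) /
    sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  sex <- matrix(c(controls$sex_m, controls$sex_f,
                  patients$sex_m, patients$sex_f),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("controls", "patients"), c("M", "F")))
  if (any(rowSums(sex) == 0) || any(colSums(sex) == 0))
    stop_named("sex table has an empty row or column")
  cs <- stats::chisq.test(sex, correct = FALSE)
  structure(list(
    age = list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df),
               pooled_sd = sqrt(sp2)),
    sex = list(chisq = unname(cs$statistic), df = unname(cs$parameter),
               p = cs$p.value, table = sex),
    lateralisation = if (!is.null(patients$lat_l))
      c(L = patients$lat_l, R = patients$lat_r) else NULL),
    class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> age: t = %.3f (df %d, p = %.3f, pooled SD %.2f)\n",
              x$age$t, x$age$df, x$age$p, x$age$pooled_sd))
  cat(sprintf("  sex: chi-square = %.3f (df %d, p = %.3f)\n",
              x$sex$chisq, x$sex$df, x$sex$p))
  if (!is.null(x$lateralisation))
    cat(sprintf("  lateralisation: %d L / %d R\n",
                x$lateralisation["L"], x$lateralisation["R"]))
  invisible(x)
}

#' Write abnormality maps as TSV
#'
#' Long format: patient, roi, band, z, max_abs_z.
#'
#' @param maps list of `abnormality_map`s.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_abnormality <- function(maps, path) {
  tabs <- lapply(maps, function(m) {
    rois <- rownames(m$z) %||% as.character(seq_len(nrow(m$z)))
    bands <- colnames(m$z) %||% as.character(seq_len(ncol(m$z)))
    data.frame(patient = m$patient_id,
               roi = rep(rois, times = length(bands)),
               band = rep(bands, each = length(rois)),
               z = as.vector(m$z),
               max_abs_z = rep(m$max_abs_z, times = length(bands)))
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
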