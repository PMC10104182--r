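# Deterministic head geometry for the synthetic study. Everything lives on /
# inside the unit sphere: sensors on the scalp (radius 1), sources on a
# nominal cortical shell (radius ~0.85). Axes: +x right, +y anterior,
# +z superior.

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

unit_rows <- function(m) m / pmax(sqrt(rowSums(m^2)), 1e-12)

# Evenly pick k rows from m (deterministic)
pick_even <- function(m, k) m[round(seq(1, nrow(m), length.out = k)), , drop = FALSE]

sensor_positions <- function(n_sensors) {
  cand <- fibonacci_sphere(4 * n_sensors)
  cand <- cand[cand[, "z"] > 0.05, , drop = FALSE]
  cand <- cand[order(-cand[, "z"], atan2(cand[, "y"], cand[, "x"])), , drop = FALSE]
  pick_even(cand, n_sensors)
}

# ROI centroids: mirrored lateral pairs plus midline unpaired regions.
roi_centroids <- function(cfg) {
  npair <- n_pairs(cfg)
  cand <- fibonacci_sphere(800)
  cand <- cand[cand[, "x"] > 0.12 & cand[, "z"] > -0.45, , drop = FALSE]
  cand <- cand[order(-cand[, "z"], cand[, "y"]), , drop = FALSE]
  right <- pick_even(cand, npair)
  left <- right; left[, "x"] <- -left[, "x"]
  yy <- seq(-0.85, 0.85, length.out = cfg$n_unpaired_rois)
  mid <- cbind(x = 0, y = yy, z = sqrt(pmax(0, 1 - yy^2)))
  list(right = right, left = left, mid = mid)
}

# Full ROI table + per-source assignment; seeded from the config root seed.
source_geometry <- function(cfg) {
  cents <- roi_centroids(cfg)
  npair <- n_pairs(cfg)
  # temporal pairs: the most inferior lateral positions
  temporal_rank <- order(cents$right[, "z"])
  temporal_pairs <- sort(temporal_rank[seq_len(cfg$n_temporal_pairs)])
  lobe_of <- function(p, temporal) {
    if (temporal) "temporal"
    else if (p["y"] > 0.25) "frontal"
    else if (p["y"] < -0.5) "occipital"
    else "parietal"
  }
  rows <- vector("list", cfg$n_rois)
  k <- 0L
  for (p in seq_len(npair)) {
    tl <- p %in% temporal_pairs
    lobe <- lobe_of(cents$right[p, ], tl)
    for (h in c("L", "R")) {
      k <- k + 1L
      cen <- if (h == "L") cents$left[p, ] else cents$right[p, ]
      rows[[k]] <- data.frame(
        roi_id = k, roi_name = sprintf("%s_%02d_%s", lobe, p, h),
        hemisphere = h, lobe = lobe, pair_id = p, temporal = tl,
        cx = cen["x"], cy = cen["y"], cz = cen["z"])
    }
  }
  for (u in seq_len(cfg$n_unpaired_rois)) {
    k <- k + 1L
    cen <- cents$mid[u, ]
    lobe <- lobe_of(cen, FALSE)
    rows[[k]] <- data.frame(
      roi_id = k, roi_name = sprintf("%s_mid%02d_M", lobe, u),
      hemisphere = "M", lobe = lobe, pair_id = NA_integer_, temporal = FALSE,
      cx = cen["x"], cy = cen["y"], cz = cen["z"])
  }
  roi <- do.call(rbind, rows)
  rownames(roi) <- NULL

  # distribute sources: every ROI gets the floor share, remainder in roi order
  base <- cfg$n_sources %/% cfg$n_rois
  counts <- rep(base, cfg$n_rois)
  extra <- cfg$n_sources - sum(counts)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  source_roi <- rep(roi$roi_id, times = counts)

  with_seed(substream_seed(cfg$seed, "geometry"), {
    cen <- as.matrix(roi[source_roi, c("cx", "cy", "cz")])
    jit <- matrix(stats::rnorm(3 * cfg$n_sources, sd = 0.06), ncol = 3)
    pos <- unit_rows(cen + jit) * 0.85
    # orientation: radial with tangential jitter. A minority of sources is
    # polarity-flipped (opposite sulcal wall) so the sign-flip step has real
    # work to do; scalp EEG is dominated by coherently oriented gyral
    # sources, so flips are the exception, not the rule.
    ori <- unit_rows(unit_rows(pos) + matrix(stats::rnorm(3 * cfg$n_sources, sd = 0.35),
                                             ncol = 3))
    flip <- ifelse(stats::runif(cfg$n_sources) < 0.2, -1, 1)
    ori <- ori * flip
  })
  list(roi = roi, source_roi = source_roi, source_positions = pos,
       orientations = ori, sensor_positions = sensor_positions(cfg$n_sensors))
}
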