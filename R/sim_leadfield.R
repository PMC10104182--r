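#' Build a synthetic leadfield
#'
#' Sensors x sources gain matrix with constrained per-source orientations.
#' Two construction modes:
#' \describe{
#'   \item{"smooth-random"}{(default) three spatially smooth random sensor
#'     field components (one per orientation axis), obtained by mixing white
#'     Gaussian gains with Gaussian kernels over sensor and source positions;
#'     the gain of a source is the field contracted with its orientation.
#'     Stands in for a realistic volume-conductor model, which is out of
#'     scope here.}
#'   \item{"sphere"}{analytic surface potential of a current dipole inside a
#'     homogeneous conducting sphere (Legendre series), used for
#'     localisation tests where ground-truth physics matters.}
#' }
#' Gains are linear in the orientation in both modes, so flipping a source's
#' normal flips its leadfield column.
#'
#' @param config a [sim_config()].
#' @param mode "smooth-random" or "sphere".
#' @return object of class `leadfield`: `$gain` (sensors x sources, uV per
#'   unit dipole moment), `$orientations` (sources x 3 unit rows),
#'   `$source_positions`, `$sensor_positions`, `$sensor_names`, `$mode`.
#' @export
make_leadfield <- function(config, mode = c("smooth-random", "sphere")) {
  mode <- match.arg(mode)
  validate_sim_config(config)
  g <- source_geometry(config)
  nsens <- config$n_sensors
  nsrc <- config$n_sources
  if (mode == "smooth-random") {
    ksrc <- exp(-as.matrix(stats::dist(g$source_positions))^2 / (2 * 0.25^2))
    ksrc <- ksrc / rowSums(ksrc)
    ksens <- exp(-as.matrix(stats::dist(g$sensor_positions))^2 / (2 * 0.5^2))
    ksens <- ksens / rowSums(ksens)
    gain <- matrix(0, nsens, nsrc)
    with_seed(substream_seed(config$seed, "leadfield"), {
      for (a in 1:3) {
        w <- matrix(stats::rnorm(nsens * nsrc), nsens, nsrc)
        field <- ksens %*% w %*% t(ksrc)
        gain <- gain + field * rep(g$orientations[, a], each = nsens)
      }
    })
    gain <- gain * (10 / stats::sd(gain))   # nominal uV scale
  } else {
    gain <- sphere_gain(g$sensor_positions, g$source_positions, g$orientations)
  }
  if (any(colSums(abs(gain)) < 1e-12))
    stop_named("leadfield has an all-zero column (source %d)",
               which(colSums(abs(gain)) < 1e-12)[1])
  names30 <- if (nsens == 30) montage_1020_30() else sprintf("Ch%02d", seq_len(nsens))
  structure(list(gain = gain, orientations = g$orientations,
                 source_positions = g$source_positions,
                 sensor_positions = g$sensor_positions,
                 sensor_names = names30, mode = mode),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d sensors x %d sources (%s mode)\n",
              nrow(x$gain), ncol(x$gain), x$mode))
  invisible(x)
}

#' Surface potential of dipoles in a homogeneous conducting sphere
#'
#' Truncated Legendre-series solution for the electric potential on the
#' surface of a homogeneous sphere (radius `R`, conductivity `sigma`)
#' generated by current dipoles inside it. The series in the source
#' eccentricity f = |r0|/R converges geometrically; `n_terms = 60` is ample
#' for f <= 0.9.
#'
#' @param sensors m x 3 sensor positions on the sphere surface.
#' @param sources n x 3 dipole positions strictly inside the sphere.
#' @param orientations n x 3 unit dipole moments.
#' @param sigma conductivity (S/m).
#' @param n_terms series truncation order.
#' @return m x n gain matrix.
#' @keywords internal
sphere_gain <- function(sensors, sources, orientations, sigma = 0.33,
                        n_terms = 60) {
  R <- sqrt(sum(sensors[1, ]^2))
  m <- nrow(sensors); n <- nrow(sources)
  gain <- matrix(0, m, n)
  rhat <- sensors / R
  for (s in seq_len(n)) {
    r0 <- sources[s, ]
    f <- sqrt(sum(r0^2)) / R
    if (f >= 1) stop_named("source %d lies outside the sphere", s)
    if (f < 1e-9) {
      r0hat <- c(0, 0, 1)   # direction irrelevant at the centre (only n=1 term)
    } else r0hat <- r0 / sqrt(sum(r0^2))
    mom <- orientations[s, ]
    m_r <- sum(mom * r0hat)
    tang <- mom - m_r * r0hat
    ct <- pmin(pmax(drop(rhat %*% r0hat), -1), 1)
    # tangential geometric factor without the sin(theta) singularity:
    # P_n^1(cos t) * cos(phi) * |m_t|  ==  P_n'(cos t) * (tang . (rhat - ct*r0hat))
    tdot <- drop(rhat %*% tang) - ct * sum(r0hat * tang)
    pm1 <- rep(1, m)          # P_0
    p <- ct                   # P_1
    dp <- rep(1, m)           # P_1'
    v <- (3 * m_r) * p + 3 * dp * tdot   # n = 1 term (f^0)
    fp <- 1
    for (nn in 2:n_terms) {
      pnew <- ((2 * nn - 1) * ct * p - (nn - 1) * pm1) / nn
      dp <- dp * ct + nn * p  # P_n' = x P_{n-1}' + n P_{n-1}
      pm1 <- p; p <- pnew
      fp <- fp * f
      if (fp < 1e-14) break
      v <- v + fp * ((2 * nn + 1) * m_r * p + ((2 * nn + 1) / nn) * dp * tdot)
    }
    gain[, s] <- v / (4 * pi * sigma * R^2)
  }
  gain * 1e3   # nominal scaling to a uV-like range
}
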