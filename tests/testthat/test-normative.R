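test_that("normative map is the elementwise mean and n-1 SD", {
  a <- matrix(0.2, 2, 5); b <- matrix(0.4, 2, 5)
  nm <- build_normative_map(list(a, b))
  expect_equal(nm$mu, matrix(0.3, 2, 5))
  expect_equal(nm$sigma, matrix(sd(c(0.2, 0.4)), 2, 5))
  expect_equal(nm$sigma[1, 1], 0.1414214, tolerance = 1e-6)
  expect_equal(nm$n_subjects, 2)
  nm2 <- build_normative_map(list(a, a, a))
  expect_true(all(nm2$sigma == 0))
  expect_error(build_normative_map(list(a, matrix(0.2, 3, 5))), "expected")
  expect_error(build_normative_map(list(a)), ">= 2 subjects")
})

test_that("normative map is permutation-invariant and row-stochastic", {
  set.seed(41)
  maps <- lapply(1:5, function(i) {
    m <- matrix(runif(20), 4, 5); m / rowSums(m)
  })
  n1 <- build_normative_map(maps)
  n2 <- build_normative_map(rev(maps))
  expect_equal(n1$mu, n2$mu)
  expect_equal(n1$sigma, n2$sigma)
  expect_equal(unname(rowSums(n1$mu)), rep(1, 4), tolerance = 1e-9)
})

test_that("spearman_rho matches a brute-force average-rank oracle under ties", {
  expect_equal(spearman_rho(1:3, c(2, 4, 6)), 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1)
  set.seed(42)
  for (i in 1:20) {
    x <- sample(1:5, 12, replace = TRUE)  # heavy ties
    y <- sample(1:5, 12, replace = TRUE)
    avg_rank <- function(v) vapply(v, function(vi)
      mean(which(sort(v) == vi)), 0)  # brute force average rank
    rx <- avg_rank(x); ry <- avg_rank(y)
    oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(spearman_rho(x, y), oracle, tolerance = 1e-12)
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), ">= 3")
})

test_that("identical epochs give robustness rho of exactly 1", {
  set.seed(43)
  seg <- matrix(rnorm(3 * 30 * 250), 3)
  ts <- ts_of(cbind(seg, seg), fs = 250)   # two identical 30-s epochs
  rep2 <- epoch_robustness(list(ts, ts_of(cbind(seg[3:1, ], seg[3:1, ]), fs = 250)),
                           epoch_duration = 30, n_epochs = 2)
  expect_equal(rep2$rho_mean, 1)
  expect_equal(rep2$rho_sd, 1)
  expect_error(epoch_robustness(list(ts), epoch_duration = 40, n_epochs = 2),
               "do not fit")
})

test_that("left-right symmetry is 1 for mirrored maps and small under the null", {
  parc <- make_parcellation(sim_config())
  nb <- 5
  set.seed(44)
  mu <- matrix(0, parc$n_rois, nb)
  right_vals <- matrix(runif(nrow(parc$pairs) * nb), ncol = nb)
  mu[parc$pairs$roi_right, ] <- right_vals
  mu[parc$pairs$roi_left, ] <- right_vals        # perfect mirror
  mu[parc$roi$hemisphere == "M", ] <- runif(6 * nb)
  nm <- list(mu = mu, sigma = mu * 0.1, n_subjects = 17)
  sym <- lr_symmetry(nm, parc)
  expect_equal(sym$rho_lr, 1)
  expect_equal(sym$n_pairs_used, 54)
  expect_length(sym$excluded_rois, 6)
  # independent left/right -> |rho| small in 95% of seeds
  rhos <- vapply(1:40, function(i) {
    set.seed(100 + i)
    mu2 <- matrix(runif(parc$n_rois * nb), ncol = nb)
    lr_symmetry(list(mu = mu2, sigma = mu2), parc)$rho_lr
  }, 0)
  expect_gte(mean(abs(rhos) <= 0.3), 0.95)
})

test_that("cross-modal correlation: self = 1, rank-reversal = -1, toy oracle", {
  set.seed(45)
  mu <- matrix(runif(25), 5, 5,
               dimnames = list(sprintf("roi%d", 1:5), sprintf("b%d", 1:5)))
  a <- list(mu = mu)
  expect_equal(unname(cross_modal_correlation(a, a)$rho), rep(1, 5))
  rev_map <- list(mu = apply(mu, 2, function(v) max(v) + min(v) - v))
  rownames(rev_map$mu) <- rownames(mu)
  expect_equal(unname(cross_modal_correlation(a, rev_map)$rho), rep(-1, 5))
  # shared-ROI alignment and pairwise drop
  b <- list(mu = mu[c(1, 2, 3, 5), ])
  rownames(b$mu) <- rownames(mu)[c(1, 2, 3, 5)]
  cm <- cross_modal_correlation(a, b)
  expect_equal(cm$n_shared, 4)
  expect_true("roi4" %in% cm$dropped)
  expect_error(cross_modal_correlation(a, list(mu = mu[1:2, ])), ">= 3 shared")
})

test_that("normative map TSV round-trips", {
  set.seed(46)
  maps <- lapply(1:4, function(i) {
    m <- matrix(runif(15), 3, 5,
                dimnames = list(c("r1", "r2", "r3"),
                                c("delta", "theta", "alpha", "beta", "gamma")))
    m / rowSums(m)
  })
  nm <- build_normative_map(maps)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_normative_map(nm, path)
  nm2 <- read_normative_map(path)
  expect_equal(nm2$mu, nm$mu)
  expect_equal(nm2$sigma, nm$sigma)
  expect_equal(nm2$n_subjects, 4)
})
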