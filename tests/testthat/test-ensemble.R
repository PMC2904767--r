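test_that("radius of gyration has its analytic limits and scaling", {
  expect_equal(radius_of_gyration(atom_row(3, 2, 1))$rg, 0)
  dumb <- analytic_fixtures(separation = 2)$dumbbell
  expect_equal(radius_of_gyration(dumb)$rg, 1)
  # direct-definition oracle on a random cloud
  set.seed(12)
  cloud <- dplyr::bind_rows(lapply(1:50, function(i) {
    atom_row(rnorm(1), rnorm(1), rnorm(1),
             elety = sample(c("C", "N", "O"), 1),
             element = sample(c("C", "N", "O"), 1), resindex = i)
  }))
  w <- c(C = 12.011, N = 14.007, O = 15.999)[cloud$element]
  co <- as.matrix(cloud[, c("x", "y", "z")])
  com <- colSums(co * w) / sum(w)
  oracle <- sqrt(sum(w * rowSums(sweep(co, 2, com)^2)) / sum(w))
  expect_equal(radius_of_gyration(cloud)$rg, oracle)
  # translation invariance and linear coordinate scaling
  shifted <- cloud
  shifted$x <- shifted$x + 50
  expect_equal(radius_of_gyration(shifted)$rg, oracle)
  scaled <- cloud
  scaled$x <- 3 * scaled$x; scaled$y <- 3 * scaled$y
  scaled$z <- 3 * scaled$z
  expect_equal(radius_of_gyration(scaled)$rg, 3 * oracle)
})

test_that("Kabsch superposition recovers rigid motions exactly", {
  m <- tiny_construct()$model
  self <- kabsch_superpose(m, m)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(self$rotation), 1, tolerance = 1e-9)
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  m2 <- m
  co <- as.matrix(m[, c("x", "y", "z")]) %*% R
  m2$x <- co[, 1] + 4; m2$y <- co[, 2] - 9; m2$z <- co[, 3] + 1
  expect_lt(backbone_rmsd(m, m2), 1e-6)
  expect_equal(backbone_rmsd(m, m2), backbone_rmsd(m2, m),
               tolerance = 1e-9)
  line <- ca_chain(rep("A", 5))   # collinear CAs degenerate
  expect_error(kabsch_superpose(line, line, atom_names = "CA"),
               class = "tailsolv_degenerate_geometry_error")
})

test_that("backbone RMSD agrees with a brute-force deviation sum", {
  tc <- tiny_construct()
  ens <- generate_ensemble(tc$model, tc$cfg)
  ms <- split(ens, ens$model)
  fit <- kabsch_superpose(ms[[1]], ms[[2]])
  bb <- c("N", "CA", "C", "O")
  a <- fit$transformed[fit$transformed$elety %in% bb, ]
  b <- ms[[2]][ms[[2]]$elety %in% bb, ]
  brute <- sqrt(mean((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2))
  expect_equal(backbone_rmsd(ms[[1]], ms[[2]]), brute, tolerance = 1e-9)
})

test_that("pairwise RMSD statistics enumerate all unordered pairs", {
  tc <- tiny_construct()
  cfg <- tc$cfg
  cfg$ensemble_size <- 3L
  ens <- generate_ensemble(tc$model, cfg)
  M <- pairwise_rmsd_matrix(ens)
  expect_equal(unname(diag(M)), rep(0, 3))
  expect_equal(M, t(M))
  st <- pairwise_rmsd_stats(ens)
  ms <- split(ens, ens$model)
  pairs <- c(backbone_rmsd(ms[[1]], ms[[2]]),
             backbone_rmsd(ms[[1]], ms[[3]]),
             backbone_rmsd(ms[[2]], ms[[3]]))
  expect_equal(st$mean_rmsd, mean(pairs))
  expect_equal(st$sd_rmsd, sd(pairs))
  expect_equal(st$n_pairs, 3L)
  # identical models give 0 +/- 0
  same <- dplyr::bind_rows(lapply(1:3, function(i) {
    m <- tc$model; m$model <- i; m
  }))
  st0 <- pairwise_rmsd_stats(same)
  expect_equal(st0$mean_rmsd, 0, tolerance = 1e-9)
  expect_equal(st0$sd_rmsd, 0, tolerance = 1e-9)
  expect_error(pairwise_rmsd_stats(tc$model),
               class = "tailsolv_ensemble_error")
})

test_that("re-sampled tails are far more variable than the jittered core", {
  tc <- tiny_construct()
  cfg <- tc$cfg
  cfg$ensemble_size <- 4L
  ens <- generate_ensemble(tc$model, cfg)
  segs <- attr(tc$model, "segments")
  tail_stat <- pairwise_rmsd_stats(ens, segs[segs$name == "ntail", ])
  core_stat <- pairwise_rmsd_stats(ens, segs[segs$name == "core", ])
  expect_gt(tail_stat$mean_rmsd, core_stat$mean_rmsd)
})

test_that("time-series statistics match a two-pass oracle", {
  M <- rbind(c(1, 2, 3), c(3, 2, 1), c(2, 2, 2))
  st <- timeseries_stats(M)
  expect_equal(st$mean, c(2, 2, 2))
  expect_equal(st$sd, apply(M, 2, sd))
  one <- timeseries_stats(M[1, , drop = FALSE])
  expect_equal(one$sd, rep(0, 3))
  long <- tidyr::pivot_longer(
    tibble::tibble(trajectory = 1:3, f1 = M[, 1], f2 = M[, 2],
                   f3 = M[, 3]),
    -trajectory, names_to = "frame", values_to = "value")
  expect_equal(timeseries_stats(long)$mean, st$mean)
  bad <- long[-1, ]
  expect_error(timeseries_stats(bad), class = "tailsolv_shape_error")
})

test_that("percentile placement counts strictly more positive values", {
  ref <- ref_distribution(c(-10, -20, -30))
  expect_equal(percentile_more_positive(ref, -25), 100 * 2 / 3)
  expect_equal(percentile_more_positive(ref, -100), 100)
  expect_equal(percentile_more_positive(ref, 0), 0)
  expect_equal(percentile_more_positive(ref, -20), 100 / 3)  # tie excluded
  set.seed(21)
  v <- rnorm(200)
  q <- seq(-2, 2, by = 0.5)
  pc <- vapply(q, function(x) percentile_more_positive(v, x), numeric(1))
  expect_equal(pc, vapply(q, function(x) 100 * sum(v > x) / 200,
                          numeric(1)))
  expect_true(all(diff(pc) <= 0))   # monotone non-increasing
})

test_that("distribution summaries match two-pass statistics", {
  expect_equal(distribution_summary(c(-1, 1))$mean, 0)
  s1 <- distribution_summary(5)
  expect_equal(s1$sd, 0)
  expect_false(s1$sd_defined)
  set.seed(4)
  v <- rnorm(77)
  s <- distribution_summary(ref_distribution(v))
  expect_equal(s$mean, mean(v))
  expect_equal(s$sd, sqrt(sum((v - mean(v))^2) / (length(v) - 1)))
  bins <- distribution_bins(v, n_bins = 12)
  expect_equal(sum(bins$count), length(v))
  # tidiers expose the same numbers
  expect_equal(glance(ref_distribution(v))$mean, mean(v))
  expect_equal(nrow(tidy(ref_distribution(v))), 77)
})
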