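# A small-but-strong setting keeps the bootstrap suites fast: the known
# sparse model has partial correlations up to 0.35, easily detected at the
# sample sizes used here.

make_curve <- function(props, cors_by_prop) {
  rows <- do.call(rbind, lapply(seq_along(props), function(i) {
    data.frame(index = "strength", proportion = props[i], replicate = 1:20,
               correlation = cors_by_prop[[i]])
  }))
  structure(list(curve = rows, original = NULL,
                 config = stability_config(n_boot = 20)),
            class = "necknet_stability_curve")
}

test_that("the CS coefficient evaluates its definition on constructed curves", {
  props <- seq(0.05, 0.75, by = 0.05)

  perfect <- make_curve(props, replicate(length(props), rep(1, 20),
                                         simplify = FALSE))
  expect_identical(unname(cs_coefficient(perfect)), max(props))

  hopeless <- make_curve(props, replicate(length(props), rep(0.2, 20),
                                          simplify = FALSE))
  expect_identical(unname(cs_coefficient(hopeless)), 0)

  # 5th percentile crosses 0.7 between 0.50 and 0.55
  cors <- lapply(props, function(p) {
    if (p <= 0.50) rep(0.95, 20) else c(rep(0.3, 3), rep(0.95, 17))
  })
  crossing <- make_curve(props, cors)
  expect_identical(unname(cs_coefficient(crossing)), 0.50)

  # raising the threshold can only lower the CS coefficient
  cfg_hi <- stability_config(n_boot = 20, cor_threshold = 0.96)
  expect_lte(cs_coefficient(crossing, cfg_hi), cs_coefficient(crossing))
})

test_that("edge bootstrap separates strong edges from noise", {
  mod <- known_sparse_model()
  set.seed(21)
  x <- as.data.frame(MASS::mvrnorm(2000, rep(0, 6), mod$sigma))
  names(x) <- paste0("f", 1:6)
  cfg <- stability_config(n_boot = 60, seed = 77)
  eci <- bootstrap_edges(x, cfg, npn = FALSE)
  truth <- mod$partial[upper.tri(mod$partial)]
  strong <- abs(truth) > 0.15
  covers_zero <- eci$edges$lower <= 0 & eci$edges$upper >= 0
  expect_true(all(!covers_zero[strong]))
  expect_true(all(eci$edges$lower <= eci$edges$boot_mean + 1e-12))
  expect_true(all(eci$edges$boot_mean <= eci$edges$upper + 1e-12))

  # independent features: point estimates mostly zero, CIs straddle zero
  set.seed(22)
  z <- as.data.frame(matrix(rnorm(200 * 6), 200, 6))
  eci0 <- bootstrap_edges(z, stability_config(n_boot = 40, seed = 5),
                          npn = FALSE)
  expect_gt(mean(eci0$edges$weight == 0), 0.5)
  expect_true(all(eci0$edges$lower <= 0 + 1e-12))

  # bit-reproducible under a fixed seed
  eci2 <- bootstrap_edges(x, cfg, npn = FALSE)
  expect_identical(eci$samples, eci2$samples)
})

test_that("case-dropping correlations are 1 when nothing is dropped and degrade on noise", {
  mod <- known_sparse_model()
  set.seed(23)
  x <- as.data.frame(MASS::mvrnorm(250, rep(0, 6), mod$sigma))
  # a proportion small enough that the subsample is the full sample
  cfg <- stability_config(n_boot = 5, drop_proportions = c(0.001),
                          seed = 3)
  cur <- casedrop_bootstrap(x, cfg, npn = FALSE)
  expect_true(all(cur$curve$correlation[cur$curve$index == "strength"] == 1))

  # hub structure at n = 1000: the strength profile is strongly varied, so
  # its correlation with the original holds up at 50 % of cases dropped
  hub <- hub_model()
  set.seed(24)
  xs <- as.data.frame(MASS::mvrnorm(1000, rep(0, 6), hub$sigma))
  cfg2 <- stability_config(n_boot = 40, drop_proportions = c(0.5), seed = 9)
  cur2 <- casedrop_bootstrap(xs, cfg2, npn = FALSE)
  sc <- cur2$curve$correlation[cur2$curve$index == "strength"]
  expect_gt(quantile(sc, 0.05, na.rm = TRUE), 0.7)

  # pure noise: the 95 %-above-0.7 stability criterion must fail at 50 %
  # dropped (correlations are weak, or undefined for empty networks)
  set.seed(25)
  zn <- as.data.frame(matrix(rnorm(300 * 6), 300, 6))
  cfg3 <- stability_config(n_boot = 30, drop_proportions = c(0.5), seed = 11)
  cur3 <- casedrop_bootstrap(zn, cfg3, npn = FALSE)
  zc <- cur3$curve$correlation[cur3$curve$index == "strength"]
  expect_lt(mean(!is.na(zc) & zc >= 0.7), 0.95)

  # too-small subsamples are skipped with a warning
  tiny <- as.data.frame(MASS::mvrnorm(12, rep(0, 6), mod$sigma))
  cfgt <- stability_config(n_boot = 2, drop_proportions = c(0.05, 0.75),
                           seed = 1)
  expect_warning(casedrop_bootstrap(tiny, cfgt, npn = FALSE), "skipped")
})

test_that("sample-size simulation shows consistency and monotone recovery", {
  mod <- known_sparse_model()
  net <- select_network(stats::cov2cor(mod$sigma), n = 5000, gamma = 0.5)

  rep1 <- sample_size_simulation(net, n_grid = c(100, 250, 500, 1000),
                                 replicates = 10, seed = 4)
  expect_true(all(rep1$sensitivity >= 0 & rep1$sensitivity <= 1))
  expect_true(all(rep1$specificity >= 0 & rep1$specificity <= 1))
  expect_gte(rep1$weight_correlation[4] + 0.02, rep1$weight_correlation[1])
  expect_gt(rep1$weight_correlation[4], 0.95)

  # empty generating network: specificity stays near 1
  empty <- select_network(diag(6), n = 100)
  rep0 <- sample_size_simulation(empty, n_grid = c(200), replicates = 10,
                                 seed = 6)
  expect_gt(rep0$specificity, 0.95)

  # reproducible
  rep2 <- sample_size_simulation(net, n_grid = c(100), replicates = 10,
                                 seed = 4)
  expect_identical(rep2$weight_correlation,
                   sample_size_simulation(net, n_grid = c(100),
                                          replicates = 10,
                                          seed = 4)$weight_correlation)
})
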