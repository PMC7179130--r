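test_that("Gauss-Seidel solves trivial and hand-derived systems", {
  # identity design returns the targets
  G <- diag(4)
  colnames(G) <- paste0("g", 1:4)
  y <- c(10, -3, 5.5, 0)
  expect_equal(as.numeric(solve_gauss_seidel(G, y)), y, tolerance = 1e-8)

  # two-compound system: closed-form solution of the 2x2 normal equations
  G2 <- cbind(ch3 = c(2, 2), ch2 = c(0, 4))
  y2 <- c(74.06, 194.30)
  x2 <- solve_gauss_seidel(G2, y2)
  expect_equal(as.numeric(x2), c(37.03, 30.06), tolerance = 1e-8)
})

test_that("Gauss-Seidel matches a direct least-squares oracle", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(15:30, 1)
    p <- sample(3:8, 1)
    G <- matrix(rpois(n * p, 1.5), n, p)
    if (qr(G)$rank < p) next
    colnames(G) <- paste0("g", seq_len(p))
    y <- rnorm(n, 100, 30)
    expect_equal(as.numeric(solve_gauss_seidel(G, y)),
                 as.numeric(ls_oracle(G, y)), tolerance = 1e-6)
  }
})

test_that("degenerate columns are reported by name", {
  G <- cbind(a = c(1, 1), b = c(0, 0))
  expect_error(solve_gauss_seidel(G, c(1, 2)), "b")
})

test_that("cross-validation is exact on noise-free linear data", {
  spec <- synth_spec(n_molecules = 80, n_groups = 8, noise_sigma = 0, seed = 3)
  design <- synth_design(spec)
  cv <- cp_cross_validate(design, k = 10, seed = 1)
  pool <- !cv$excluded
  expect_gt(sum(pool), 40)
  expect_equal(cv$cp_cv[pool], cv$cp_exp[pool], tolerance = 1e-6)
  s <- cp_statistics(cv$cp_cv[pool], cv$cp_exp[pool])
  expect_equal(s$r2, 1, tolerance = 1e-9)
  expect_lt(s$std_dev, 1e-6)
})

test_that("a compound owning an under-supported group is excluded from CV", {
  G <- rbind(c(2, 0), c(3, 0), c(1, 0), c(2, 0), c(2, 1))
  colnames(G) <- c("common", "unique")
  design <- cp_design_from_counts(G, c(20, 30, 10, 20, 25))
  cv <- cp_cross_validate(design, k = 5, seed = 1)
  expect_true(cv$excluded[5])
  expect_false(any(cv$excluded[1:4]))
})

test_that("cross-validation rejects k < 2", {
  design <- synth_design(synth_spec(n_molecules = 40, n_groups = 4, seed = 1))
  expect_error(cp_cross_validate(design, k = 1), "at least 2")
})

test_that("enlarging the training folds never adds CV exclusions", {
  spec <- synth_spec(n_molecules = 60, n_groups = 10, noise_sigma = 2, seed = 9)
  d_small <- synth_design(spec)
  spec_big <- synth_spec(n_molecules = 120, n_groups = 10, noise_sigma = 2,
                         seed = 9)
  d_big <- synth_design(spec_big)
  # identical fold ids for the shared first 60 compounds; the added rows are
  # spread over the same folds and only ever add support
  folds_small <- rep_len(1:5, 60)
  folds_big <- c(folds_small, rep_len(1:5, 60))
  cv_small <- cp_cross_validate(d_small, k = 5, folds = folds_small)
  cv_big <- cp_cross_validate(d_big, k = 5, folds = folds_big)
  expect_lte(sum(cv_big$excluded[1:60]), sum(cv_small$excluded))
})

test_that("statistics match hand arithmetic", {
  s <- cp_statistics(c(110, 190), c(100, 200))
  expect_equal(s$mapd, 7.5)
  expect_equal(s$avg_dev, 10)

  exp <- c(100, 150, 200, 250)
  s2 <- cp_statistics(exp, exp)
  expect_equal(s2$r2, 1)
  expect_equal(s2$mapd, 0)

  s3 <- cp_statistics(exp + 5, exp)
  expect_equal(s3$r2, 1)              # translation invariance
  expect_equal(s3$avg_dev, 5)
  expect_equal(s3$std_dev, 5 * sqrt(4 / 3))  # n-1 denominator

  expect_error(cp_statistics(numeric(0), numeric(0)), "at least two")
  expect_error(cp_statistics(c(1, 2), c(0, 2)), "non-zero")
})

test_that("zero-noise fitting recovers the true contributions", {
  spec <- synth_spec(n_molecules = 100, n_groups = 12, noise_sigma = 0,
                     seed = 11)
  fit <- cp_fit(design = synth_design(spec), k = 10, seed = 2)
  got <- tidy(fit)
  truth <- spec$true_contributions[got$key]
  expect_lt(max(abs(got$contribution - truth)), 1e-6)
  expect_equal(nrow(fit$outliers), 0)
})

test_that("noisy fitting is unbiased over replicates", {
  errs <- replicate(50, {
    spec <- synth_spec(n_molecules = 60, n_groups = 6, noise_sigma = 8,
                       seed = sample.int(1e6, 1))
    d <- synth_design(spec)
    x <- solve_gauss_seidel(d)
    mean(x[names(spec$true_contributions)] - spec$true_contributions)
  })
  expect_lt(abs(mean(errs)), 1.5)   # ~0 bias; sd of the mean is well below 1
})

test_that("an implanted gross error is removed by the outlier loop", {
  spec <- synth_spec(n_molecules = 120, n_groups = 10, noise_sigma = 4,
                     seed = 21)
  d <- generate_synthetic_training(spec)
  G <- attr(d, "counts")
  cp <- d$cp
  cp[17] <- cp[17] + 10 * 4 * 3     # far beyond 3 cross-validated sigmas
  design <- cp_design_from_counts(G, cp)
  fit <- cp_fit(design = design, k = 10, seed = 5)
  expect_equal(fit$outliers$compound, "synth_0017")

  # removal strictly decreases the training standard deviation
  x_all <- solve_gauss_seidel(design)
  sd_all <- sqrt(sum((as.numeric(G %*% x_all) - cp)^2) / (length(cp) - 1))
  expect_lt(fit$stats$std_dev, sd_all)
})

test_that("fit statistics only cover compounds whose groups are all valid", {
  # two compounds carry a group supported by a single molecule
  set.seed(33)
  G <- matrix(rpois(40 * 4, 2), 40, 4)
  G[, 4] <- 0
  G[7, 4] <- 1                       # support 1 < 3
  colnames(G) <- paste0("g", 1:4)
  rownames(G) <- sprintf("m%02d", 1:40)
  truth <- c(30, 50, -10, 100)
  y <- as.numeric(G %*% truth) + rnorm(40, 0, 2)
  fit <- cp_fit(design = cp_design_from_counts(G, y), k = 5, seed = 1)
  expect_equal(fit$stats$n_total, 40)
  expect_equal(fit$stats$n_fit, 39)
  expect_false(fit$contributions$valid[fit$contributions$key == "g4"])
  expect_lte(fit$stats$n_cv, fit$stats$n_fit)
})

test_that("fit accessors behave like broom and ggplot methods", {
  spec <- synth_spec(n_molecules = 60, n_groups = 6, noise_sigma = 3, seed = 8)
  fit <- cp_fit(design = synth_design(spec), k = 5, seed = 4)
  td <- tidy(fit)
  expect_true(all(c("key", "contribution", "valid") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$q2 <= gl$r2 + 0.05)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("a fitted table round-trips through TSV and predicts", {
  train <- cp_fixtures()
  train <- train[train$source_table %in% c("T4", "T5"), ]
  train <- tibble::tibble(name = train$name, smiles = train$smiles,
                          cp = train$cp_exp)
  fit <- cp_fit(train, k = 5, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_cp_table(as_cp_table(fit), path)
  tab <- cp_table("liquid", file = path)
  p <- cp_predict("CCCCCC", table = tab, invalid_groups = "allow")
  expect_false(is.na(p$cp))
  expect_lt(abs(p$cp - 197.66), 15)  # near the experimental hexane value
})
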