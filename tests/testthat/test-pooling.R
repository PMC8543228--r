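test_that("sleep masking lifts a waking-day fit onto 3 coordinates", {
  f <- mk_fit(c(z2 = -0.1, z3 = -0.5),
              matrix(c(0.01, 0.002, 0.002, 0.02), 2,
                     dimnames = list(c("z2", "z3"), c("z2", "z3"))))
  m <- mask_missing_sleep(f)
  expect_equal(unname(m$gamma), c(0, -0.1, -0.5))
  expect_equal(m$vcov_gamma["z1", "z1"], 1e6)
  expect_equal(m$vcov_gamma["z1", "z2"], 0)
  expect_equal(m$vcov_gamma[2:3, 2:3], f$vcov_gamma)
  fs <- mk_fit(c(z1 = 0.1, z2 = -0.1, z3 = -0.5), rep(0.01, 3),
               measures_sleep = TRUE)
  expect_error(mask_missing_sleep(fs), "measures sleep")
})

test_that("two identical studies pool to themselves with Psi ~ 0", {
  f <- mk_fit(c(z2 = -0.3, z3 = -0.6), c(0.01, 0.02), study = "a")
  g <- f; g$study <- "b"
  for (m in c("reml", "mm")) {
    pm <- pool_random_effects(list(f, g), method = m)
    expect_equal(pm$gamma, f$gamma, tolerance = 1e-6)
    expect_lt(max(abs(pm$Psi)), 1e-6)
    expect_equal(pm$het$Q, c(0, 0), tolerance = 1e-12)
    expect_equal(pm$het$I2, c(0, 0))
  }
})

test_that("univariate pooling matches the DerSimonian-Laird closed form", {
  # hand computation: theta = (0, 4), SE = (1, 1):
  # Q = 8, I2 = 87.5%, tau2_DL = (8-1)/(2-2/2) = 7, mu = 2, se = 2
  f1 <- mk_fit(c(z2 = 0), 1, study = "a")
  f2 <- mk_fit(c(z2 = 4), 1, study = "b")
  pm <- pool_random_effects(list(f1, f2), method = "mm")
  expect_equal(unname(pm$gamma), 2)
  expect_equal(unname(pm$Psi[1, 1]), 7)
  expect_equal(unname(sqrt(diag(pm$vcov))), 2)
  het <- heterogeneity_stats(list(f1, f2))
  expect_equal(het$Q, 8)
  expect_equal(het$I2, 87.5)
  # theta = (0, 1): Q = 0.5, I2 = 0
  het2 <- heterogeneity_stats(list(f1, mk_fit(c(z2 = 1), 1, study = "b")))
  expect_equal(het2$Q, 0.5)
  expect_equal(het2$I2, 0)
})

test_that("REML pooling agrees with metafor", {
  skip_if_not_installed("metafor")
  # univariate
  f1 <- mk_fit(c(z2 = 0), 1, study = "a")
  f2 <- mk_fit(c(z2 = 4), 1, study = "b")
  pm <- pool_random_effects(list(f1, f2), method = "reml")
  r <- metafor::rma(yi = c(0, 4), vi = c(1, 1), method = "REML")
  expect_equal(unname(pm$gamma), unname(as.vector(r$b)), tolerance = 1e-4)
  expect_equal(unname(pm$Psi[1, 1]), r$tau2, tolerance = 1e-3)
  expect_equal(unname(sqrt(diag(pm$vcov))), r$se, tolerance = 1e-3)
  # bivariate, unstructured between-study covariance
  th <- rbind(c(-0.10, -0.60), c(-0.30, -0.80), c(0.05, -0.50))
  S <- matrix(c(0.02, 0.005, 0.005, 0.03), 2)
  fits <- lapply(1:3, function(i)
    mk_fit(c(z2 = th[i, 1], z3 = th[i, 2]), S, study = paste0("s", i)))
  pm2 <- pool_random_effects(fits, method = "reml")
  dat <- data.frame(yi = as.vector(t(th)),
                    coord = rep(c("z2", "z3"), 3),
                    study = rep(1:3, each = 2))
  V <- as.matrix(Matrix::bdiag(S, S, S))
  rv <- suppressWarnings(metafor::rma.mv(
    yi, V = V, mods = ~ coord - 1, random = ~ coord | study,
    struct = "UN", data = dat))
  expect_equal(unname(pm2$gamma), unname(as.vector(rv$b)),
               tolerance = 1e-3)
})

test_that("pooled estimates stay in the convex hull and respond to
           precision", {
  set.seed(40)
  fits <- lapply(1:5, function(i)
    mk_fit(c(z2 = rnorm(1, -0.3, 0.2), z3 = rnorm(1, -0.6, 0.2)),
           c(0.01 * i, 0.02 * i), study = paste0("s", i)))
  pm <- pool_random_effects(fits, method = "mm")
  th <- sapply(fits, function(f) f$gamma)
  expect_true(all(pm$gamma >= apply(th, 1, min) - 1e-12))
  expect_true(all(pm$gamma <= apply(th, 1, max) + 1e-12))
  # inflating study 1's vcov moves the pool toward the others
  f1big <- fits[[1]]
  f1big$vcov_gamma <- f1big$vcov_gamma * 50
  pm2 <- pool_random_effects(c(list(f1big), fits[-1]), method = "mm")
  rest <- pool_random_effects(fits[-1], method = "mm")
  expect_true(all(abs(pm2$gamma - rest$gamma) <=
                    abs(pm$gamma - rest$gamma) + 1e-12))
})

test_that("masked studies carry negligible weight on the sleep balance", {
  cfgh <- sim_config(n = 800, zero_p = 0,
                     baseline = list(family = "exponential", rate = 0.05))
  cfgw <- sim_config(n = 800, measures_sleep = TRUE, zero_p = 0,
                     baseline = list(family = "exponential", rate = 0.05))
  fw1 <- fit_compositional_cox(generate_cohort(cfgw, seed = 41))
  fw2 <- fit_compositional_cox(generate_cohort(cfgw, seed = 42))
  fh <- fit_compositional_cox(generate_cohort(cfgh, seed = 43))
  p2 <- pool_random_effects(list(fw1, fw2), method = "mm")
  p3 <- pool_random_effects(list(fw1, fw2, mask_missing_sleep(fh)),
                            method = "mm")
  expect_lt(abs(p2$gamma[["z1"]] - p3$gamma[["z1"]]), 1e-3)
  # mask variance choice is immaterial above the floor
  p38 <- pool_random_effects(
    list(fw1, fw2, mask_missing_sleep(fh, 1e8)), method = "mm")
  expect_lt(abs(p38$gamma[["z1"]] - p3$gamma[["z1"]]), 1e-4)
  pr6 <- pool_random_effects(list(fw1, fw2, mask_missing_sleep(fh)))
  pr8 <- pool_random_effects(list(fw1, fw2, mask_missing_sleep(fh, 1e8)))
  expect_lt(abs(pr6$gamma[["z1"]] - pr8$gamma[["z1"]]), 1e-4)
})

test_that("random-effects truth is recovered from simulated study sets", {
  # draw study estimates directly from theta_i ~ N(mu, S_i + Psi)
  set.seed(44)
  mu <- c(z2 = -0.25, z3 = -0.55)
  Psi <- matrix(c(0.04, 0.01, 0.01, 0.02), 2)
  k <- 20
  reps <- 30
  est <- matrix(NA_real_, reps, 2)
  psi_est <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    fits <- lapply(seq_len(k), function(i) {
      S <- diag(runif(2, 0.005, 0.02))
      ch <- chol(S + Psi)
      mk_fit(setNames(mu + drop(rnorm(2) %*% ch), names(mu)), S,
             study = paste0("s", i))
    })
    pm <- pool_random_effects(fits, method = "reml")
    est[r, ] <- pm$gamma
    psi_est[r, ] <- diag(pm$Psi)
  }
  mc_se <- apply(est, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(est) - mu) < 3 * mc_se + 0.01))
  expect_equal(colMeans(psi_est), diag(Psi), tolerance = 0.35)
})

test_that("leave-one-out and stratified pools are bookkept correctly", {
  f <- function(i, g2, dev) mk_fit(c(z2 = g2, z3 = -0.5), c(0.01, 0.01),
                                   study = paste0("s", i), device = dev)
  same <- lapply(1:3, function(i) f(i, -0.3, "hip"))
  loo <- leave_one_out(same, method = "mm")
  full <- pool_random_effects(same, method = "mm")
  for (nm in paste0("drop:s", 1:3))
    expect_equal(loo[[nm]]$gamma, full$gamma, tolerance = 1e-9)
  # one outlier among 5: dropping it moves z2 the most
  fits5 <- c(lapply(1:4, function(i) f(i, -0.3, "hip")),
             list(f(5, 1.5, "wrist")))
  # the wrist stratum has a single study -> passthrough warning
  loo5 <- suppressWarnings(leave_one_out(fits5, method = "mm"))
  shifts <- sapply(paste0("drop:s", 1:5), function(nm)
    abs(loo5[[nm]]$gamma[["z2"]] - pool_random_effects(
      fits5, method = "mm")$gamma[["z2"]]))
  expect_equal(unname(which.max(shifts)), 5)
  expect_identical(sort(loo5[["hip"]]$studies), paste0("s", 1:4))
  expect_warning(pool_random_effects(fits5[5]), "single study")
  expect_identical(loo5[["wrist"]]$k, 1L)
})

test_that("pooled models round-trip through JSON at full precision", {
  f1 <- mk_fit(c(z2 = -1 / 3, z3 = -0.123456789123456), c(0.01, 0.02),
               study = "a")
  f2 <- mk_fit(c(z2 = -0.2, z3 = -0.4), c(0.015, 0.025), study = "b")
  pm <- pool_random_effects(list(f1, f2), method = "mm")
  path <- tempfile(fileext = ".json")
  write_pooled_model(pm, path)
  back <- read_pooled_model(path)
  expect_identical(back$gamma, pm$gamma)
  expect_identical(back$vcov, pm$vcov)
  expect_identical(back$Psi, pm$Psi)
})
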