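test_that("hazard ratios follow the log-linear ilr-difference algebra", {
  hip <- hip_model()
  ref <- composition(2, 229, 729)
  expect_equal(unname(hazard_ratio(hip, ref, ref)), c(1, 1, 1))
  # worked points against the published hip coefficients
  expect_equal(
    round(hazard_ratio(hip, composition(3, 375, 582), ref)[["hr"]], 2),
    0.70)
  expect_equal(
    round(hazard_ratio(hip, composition(13, 330, 617), ref)[["hr"]], 2),
    0.70)
  # antisymmetry and transitivity over random pairs
  set.seed(50)
  for (i in 1:20) {
    a <- close_composition(rexp(3) + 0.1, 960)
    b <- close_composition(rexp(3) + 0.1, 960)
    c3 <- close_composition(rexp(3) + 0.1, 960)
    expect_equal(hazard_ratio(hip, a, b)[["hr"]],
                 1 / hazard_ratio(hip, b, a)[["hr"]], tolerance = 1e-12)
    expect_equal(hazard_ratio(hip, a, b)[["hr"]] *
                   hazard_ratio(hip, b, c3)[["hr"]],
                 hazard_ratio(hip, a, c3)[["hr"]], tolerance = 1e-12)
  }
  # a waking-day model cannot assess sleep-including compositions
  expect_error(
    hazard_ratio(hip, composition(3, 375, 582, sleep = 480),
                 composition(2, 229, 729, sleep = 480)),
    "waking-day")
})

test_that("unit hazard ratios are exp(coefficient) with Wald intervals", {
  tab <- unit_hazard_ratios(hip_model())
  expect_equal(tab$HR, exp(tab$coef))
  expect_equal(tab$coef, c(-0.073, -0.681))
  expect_true(all(tab$lo < tab$HR & tab$HR < tab$hi))
  null <- pooled_model_from_coefficients(c(z2 = 0, z3 = 0))
  expect_equal(unit_hazard_ratios(null)$HR, c(1, 1))
})

test_that("interval width shrinks as the coefficient covariance shrinks", {
  hip <- hip_model()
  smaller <- hip
  smaller$vcov <- hip$vcov * 0.25
  a <- composition(30, 330, 600)
  ref <- composition(2, 358, 600)
  h1 <- hazard_ratio(hip, a, ref)
  h2 <- hazard_ratio(smaller, a, ref)
  expect_lt(h2[["hi"]] - h2[["lo"]], h1[["hi"]] - h1[["lo"]])
})

test_that("reference selection lands on the requested Mahalanobis
           contour", {
  # samples with exact mean 0 and identity covariance by construction
  set.seed(51)
  n <- 500
  x <- matrix(rnorm(2 * n), n)
  x <- scale(x, center = TRUE, scale = FALSE)
  x <- x %*% solve(chol(cov(x)))
  colnames(x) <- c("z2", "z3")
  sel <- select_reference(x, coverage = 0.75, direction = c(-1, -1))
  expect_equal(sqrt(sum(sel$z^2)), sqrt(qchisq(0.75, 2)),
               tolerance = 1e-9)
  expect_equal(sel$mahalanobis2, qchisq(0.75, 2), tolerance = 1e-6)
  # coverage 0 degenerates to the centre
  sel0 <- select_reference(x, coverage = 0, direction = c(1, 0))
  expect_equal(unname(sel0$z), c(0, 0), tolerance = 1e-9)
  # low-(z2, z3) direction yields low MVPA and low LIPA share
  set.seed(52)
  cloud <- ilr_forward(compositions(generate_cohort(
    sim_config(n = 2000, zero_p = 0), seed = 52)))
  selc <- select_reference(cloud, 0.75, c(-1, -1))
  centre <- ilr_inverse(colMeans(cloud), 960)
  expect_lt(selc$composition[["mvpa"]], centre[["mvpa"]])
  expect_lt(selc$composition[["lipa"]] / selc$composition[["sb"]],
            centre[["lipa"]] / centre[["sb"]])
  expect_error(select_reference(x[1:5, ]), "at least 10")
})

test_that("dose-response curves honour reference ratios and monotone
           reallocation", {
  hip <- hip_model()
  ref <- composition(2, 229, 729)
  cur <- dose_response(hip, ref, "mvpa", grid = c(2, seq(5, 60, 5)))
  expect_equal(cur$hr[cur$focal_min == 2], 1, tolerance = 1e-12)
  expect_true(all(diff(cur$hr) < 0))   # gamma2 < 0: more MVPA, lower HR
  # non-focal parts keep the reference's mutual ratio
  expect_equal(cur$lipa / cur$sb, rep(229 / 729, nrow(cur)),
               tolerance = 1e-9)
  # singleton grid equals hazard_ratio directly
  one <- dose_response(hip, ref, "mvpa", grid = 30)
  expect_equal(one$hr,
               hazard_ratio(hip, close_composition(
                 c(mvpa = 30, lipa = 229 * 930 / 958,
                   sb = 729 * 930 / 958), 960), ref)[["hr"]],
               tolerance = 1e-9)
  # wrist model: sleep reallocation is nearly flat with CI spanning 1
  wr <- wrist_model()
  ref4 <- composition(20, 60, 880, sleep = 480)
  slp <- dose_response(wr, ref4, "sleep",
                       grid = seq(360, 600, 30))
  expect_true(all(abs(log(slp$hr)) < 0.15))
  expect_true(all(slp$lo <= 1 & slp$hi >= 1))
  # infeasible grid points are dropped with a warning
  expect_warning(
    dose_response(hip, ref, "mvpa", grid = c(30, 959.5),
                  fixed_sb = 600), "infeasible")
})

test_that("curves and surfaces are invariant to the unit of time", {
  hip <- hip_model()
  ref_min <- composition(2, 229, 729)
  ref_hr <- close_composition(c(mvpa = 2, lipa = 229, sb = 729) / 60, 16)
  h_min <- hazard_ratio(hip, composition(30, 215, 715), ref_min)
  h_hr <- hazard_ratio(hip, close_composition(
    c(mvpa = 30, lipa = 215, sb = 715) / 60, 16), ref_hr)
  expect_equal(h_min, h_hr, tolerance = 1e-9)
})

test_that("the joint surface masks infeasible cells and matches pointwise
           hazard ratios", {
  hip <- hip_model()
  ref <- composition(2, 229, 729)
  surf <- joint_heatmap(hip, ref, mvpa_grid = seq(0, 120, 10),
                        sb_grid = seq(420, 900, 40))
  expect_true(all(is.na(surf$hr[!surf$feasible])))
  expect_true(all(surf$lipa[!surf$feasible] <= 0))
  # a surface cell equals the direct hazard ratio of its composition
  i <- which(surf$feasible)[100]
  expect_equal(surf$hr[i],
               hazard_ratio(hip, close_composition(
                 c(mvpa = surf$mvpa[i], lipa = surf$lipa[i],
                   sb = surf$sb[i]), 960), ref)[["hr"]],
               tolerance = 1e-9)
  # reference cell has HR 1
  surf2 <- joint_heatmap(hip, composition(10, 350, 600),
                         mvpa_grid = 10, sb_grid = 600)
  expect_equal(surf2$hr, 1, tolerance = 1e-12)
  # along a LIPA isotime line, raising MVPA at the expense of SB lowers
  # the HR when both balances have negative coefficients
  iso <- surf[surf$feasible & abs(surf$lipa - 240) < 1e-9, ]
  iso <- iso[order(iso$mvpa), ]
  if (nrow(iso) > 2) expect_true(all(diff(iso$hr) < 0))
  expect_error(joint_heatmap(hip, ref, mvpa_grid = 900, sb_grid = 900),
               "infeasible")
})

test_that("reallocation solving inverts the hazard-ratio curve", {
  hip <- hip_model()
  ref <- composition(2, 358, 600)
  sol <- solve_reallocation(hip, ref, 0.90, "mvpa_for_sb")
  expect_equal(sol$attained_hr, 0.90, tolerance = 1e-6)
  # round trip: applying the solved reallocation reproduces the target
  moved <- close_composition(
    c(mvpa = 2 + sol$minutes_exact, lipa = 358,
      sb = 600 - sol$minutes_exact), attr(ref, "total"))
  expect_equal(hazard_ratio(hip, moved, ref)[["hr"]], 0.90,
               tolerance = 1e-6)
  expect_true(sol$ci_low < sol$minutes && sol$minutes < sol$ci_high)
  # target 1 needs no change
  expect_equal(solve_reallocation(hip, ref, 1, "mvpa_for_sb")$minutes, 0)
  # unreachable targets report the attained infimum
  weak <- pooled_model_from_coefficients(c(z2 = -1e-4, z3 = -1e-4))
  nosol <- solve_reallocation(weak, ref, 0.5, "lipa_for_sb")
  expect_true(is.na(nosol$minutes))
  expect_gt(nosol$hr_infimum, 0.5)
})
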