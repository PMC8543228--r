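# Compositional effect estimation from a pooled model.
#
# The log hazard ratio between two compositions is linear in the
# difference of their ilr coordinates, log HR = gamma' (z_a - z_b), so
# Wald intervals on the log scale are exact given the coefficient
# covariance (the compositions are treated as fixed).

.effect_z <- function(model, comp) {
  z <- ilr_forward(comp)
  nm <- names(z)
  if (!all(nm %in% names(model$gamma)))
    stop("model (coordinates ", paste(names(model$gamma), collapse = ","),
         ") does not cover composition coordinates ",
         paste(nm, collapse = ","),
         if (!"z1" %in% names(model$gamma))
           " -- a waking-day model cannot assess sleep-including compositions")
  z
}

.hr_core <- function(model, dz, conf = 0.95) {
  g <- model$gamma[names(dz)]
  est <- sum(g * dz)
  V <- model$vcov
  se <- if (is.null(V) || any(is.na(V[names(dz), names(dz)]))) NA_real_
        else sqrt(drop(t(dz) %*% V[names(dz), names(dz)] %*% dz))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  c(hr = exp(est), lo = exp(est - zq * se), hi = exp(est + zq * se))
}

#' Hazard ratio between two compositions
#'
#' HR = exp(sum_i gamma_i (z_i(comp) - z_i(ref))) with a Wald interval on
#' the log scale using the pooled coefficient covariance.
#'
#' @param model A `pooled_model` (or any list with `gamma` and `vcov`).
#' @param comp,ref Compositions of the same arity and total.
#' @param conf Confidence level (default 0.95).
#' @return Named vector `hr`, `lo`, `hi` (`lo`/`hi` are `NA` when the
#'   model carries no covariance).
#' @examples
#' hip <- pooled_model_from_coefficients(c(z2 = -0.073, z3 = -0.681))
#' hazard_ratio(hip, composition(3, 375, 582), composition(2, 229, 729))
#' @export
hazard_ratio <- function(model, comp, ref, conf = 0.95) {
  za <- .effect_z(model, comp)
  zb <- .effect_z(model, ref)
  if (length(za) != length(zb))
    stop("comp and ref have different arity")
  .hr_core(model, za - zb, conf)
}

#' Per-coordinate unit hazard ratios
#'
#' exp(gamma_i) for a one-unit increase in each ilr balance, with Wald
#' p-values and confidence intervals from the covariance diagonal.
#'
#' @param model A `pooled_model`.
#' @param conf Confidence level.
#' @return Data frame: `coord`, `coef`, `se`, `HR`, `p`, `lo`, `hi`.
#' @export
unit_hazard_ratios <- function(model, conf = 0.95) {
  g <- model$gamma
  se <- if (is.null(model$vcov)) rep(NA_real_, length(g))
        else sqrt(diag(model$vcov))[names(g)]
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  data.frame(coord = names(g), coef = unname(g), se = unname(se),
             HR = unname(exp(g)),
             p = unname(2 * stats::pnorm(-abs(g / se))),
             lo = unname(exp(g - zq * se)),
             hi = unname(exp(g + zq * se)),
             row.names = NULL)
}

#' Select a reference composition on a Mahalanobis contour
#'
#' Fits a bivariate normal to observed (z2, z3) coordinates, then returns
#' the inverse-ilr of the point mu + r * Sigma^(1/2) u, where u is the
#' requested unit direction in standardised coordinates and r^2 the
#' chi-square(2) quantile at `coverage`.  The point lies exactly on the
#' constant-Mahalanobis contour enclosing `coverage` of the fitted
#' distribution, i.e. a composition that is unusual in the requested
#' direction but still supported by the data.
#'
#' @param ilr_samples Matrix/data frame with columns z2, z3 (>= 10 rows).
#' @param coverage Contour coverage probability (default 0.75).
#' @param direction Direction in standardised coordinates; the default
#'   (-1, -1) targets low MVPA and a low LIPA:SB balance.
#' @param total Waking-day total for the returned composition.
#' @return List: `composition`, `z` (the contour point), `mu`, `sigma`,
#'   `coverage`, `mahalanobis2`.
#' @export
select_reference <- function(ilr_samples, coverage = 0.75,
                             direction = c(-1, -1), total = 960) {
  zm <- as.matrix(ilr_samples)
  if (nrow(zm) < 10) stop("need at least 10 ilr samples")
  if (all(direction == 0)) stop("direction must be nonzero")
  mu <- colMeans(zm)
  Sig <- stats::cov(zm)
  ev <- eigen(Sig, symmetric = TRUE)
  if (min(ev$values) <= 1e-12) stop("singular ilr covariance")
  half <- ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors)
  u <- direction / sqrt(sum(direction^2))
  r <- sqrt(stats::qchisq(coverage, df = 2))
  zpt <- drop(mu + r * half %*% u)
  names(zpt) <- c("z2", "z3")
  d2 <- drop(t(zpt - mu) %*% solve(Sig) %*% (zpt - mu))
  list(composition = ilr_inverse(zpt, total = total), z = zpt,
       mu = mu, sigma = Sig, coverage = coverage, mahalanobis2 = d2)
}

#' Dose-response reallocation curve
#'
#' Varies the time in one focal behaviour over a grid and reports the
#' hazard ratio of each reallocated composition against the reference.
#' By default the non-focal behaviours keep the mutual ratios they have
#' in the reference (proportional reallocation).  With `fixed_sb` set
#' (focal MVPA only), SB is held at that value and LIPA absorbs the
#' remainder, one curve per SB level.
#'
#' @param model A `pooled_model`.
#' @param ref Reference composition.
#' @param focal Part name to vary (`"sleep"`, `"mvpa"`, `"lipa"`, `"sb"`).
#' @param grid Minutes/day values for the focal part.
#' @param fixed_sb Optional SB minutes for the two-behaviour mode.
#' @param conf Confidence level.
#' @return Data frame of class `effect_curve`: part columns, `focal`,
#'   `focal_min`, `hr`, `lo`, `hi`, `is_ref`; infeasible grid points are
#'   dropped with a warning.
#' @export
dose_response <- function(model, ref, focal, grid, fixed_sb = NULL,
                          conf = 0.95) {
  ref <- close_composition(ref)
  total <- attr(ref, "total")
  parts <- names(ref)
  if (!focal %in% parts) stop("focal part '", focal, "' not in composition")
  if (any(grid <= 0 | grid >= total)) stop("grid must lie within (0, total)")
  rows <- lapply(grid, function(t) {
    x <- unclass(ref)
    if (is.null(fixed_sb)) {
      others <- setdiff(parts, focal)
      rem <- total - t
      if (rem <= 0) return(NULL)
      x[focal] <- t
      x[others] <- x[others] * rem / sum(x[others])
    } else {
      if (focal != "mvpa" || !"sb" %in% parts)
        stop("fixed_sb mode varies mvpa with sb held fixed")
      lipa <- total - t - fixed_sb -
        if ("sleep" %in% parts) x["sleep"] else 0
      if (lipa <= 0) return(NULL)
      x["mvpa"] <- t; x["sb"] <- fixed_sb; x["lipa"] <- lipa
    }
    if (any(x <= 0)) return(NULL)
    h <- hazard_ratio(model, close_composition(x, total), ref, conf)
    c(x, focal_min = t, h)
  })
  keep <- !vapply(rows, is.null, TRUE)
  if (any(!keep))
    warning(sum(!keep), " grid point(s) infeasible (non-positive part)",
            " and dropped")
  out <- as.data.frame(do.call(rbind, rows[keep]))
  out$focal <- focal
  out$is_ref <- abs(out$focal_min - ref[focal]) < 1e-9
  class(out) <- c("effect_curve", class(out))
  attr(out, "ref") <- ref
  out
}

#' Joint waking-day hazard-ratio surface
#'
#' Evaluates the hazard ratio against `ref` over an MVPA x SB grid with
#' LIPA as the remaining waking time; cells with non-positive implied
#' LIPA are marked infeasible.  Cells sharing a LIPA value form the
#' isotime lines of the corresponding heat map.
#'
#' @param model A `pooled_model` over (z2, z3) at least.
#' @param ref Waking-day (3-part) reference composition.
#' @param mvpa_grid,sb_grid Minutes/day grids (defaults 0-120 by 1 and
#'   420-900 by 5; zero MVPA is clamped to 0.5 min to stay in the
#'   simplex interior).
#' @param waking_total Waking-day total (default 960 min = 16 h,
#'   i.e. 8 h sleep).
#' @param conf Confidence level.
#' @return Long data frame of class `effect_surface`: `mvpa`, `sb`,
#'   `lipa`, `feasible`, `hr`, `lo`, `hi`.
#' @export
joint_heatmap <- function(model, ref, mvpa_grid = seq(0, 120, 1),
                          sb_grid = seq(420, 900, 5), waking_total = 960,
                          conf = 0.95) {
  ref <- close_composition(ref)
  if (length(ref) != 3) stop("heat maps are waking-day surfaces; 3 parts")
  mvpa_grid <- pmax(mvpa_grid, 0.5)
  g <- expand.grid(mvpa = mvpa_grid, sb = sb_grid)
  g$lipa <- waking_total - g$mvpa - g$sb
  g$feasible <- g$lipa > 0
  if (!any(g$feasible)) stop("entirely infeasible grid")
  zr <- ilr_forward(ref)
  hr <- lo <- hi <- rep(NA_real_, nrow(g))
  f <- which(g$feasible)
  zc <- ilr_forward(as.matrix(g[f, c("mvpa", "lipa", "sb")]))
  dz <- sweep(zc, 2, zr[colnames(zc)])
  gam <- model$gamma[colnames(dz)]
  est <- drop(dz %*% gam)
  V <- model$vcov
  if (!is.null(V) && !any(is.na(V[colnames(dz), colnames(dz)]))) {
    se <- sqrt(rowSums((dz %*% V[colnames(dz), colnames(dz)]) * dz))
  } else se <- NA_real_
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  hr[f] <- exp(est)
  lo[f] <- exp(est - zq * se)
  hi[f] <- exp(est + zq * se)
  g$hr <- hr; g$lo <- lo; g$hi <- hi
  class(g) <- c("effect_surface", class(g))
  attr(g, "ref") <- ref
  g
}

#' Minutes of reallocation needed to reach a target hazard ratio
#'
#' Solves for the number of minutes delta moved out of sedentary time
#' into MVPA (LIPA fixed) or into LIPA (MVPA fixed) such that the hazard
#' ratio of the reallocated composition against `ref` equals
#' `target_hr`, by bracketed root search on delta in (0, SB - 1).
#' Confidence bounds are the delta solving the same equation on the
#' Wald upper/lower HR-bound curves.
#'
#' @param model A `pooled_model`.
#' @param ref Waking-day reference composition.
#' @param target_hr Target hazard ratio in (0, 1].
#' @param mode `"mvpa_for_sb"` or `"lipa_for_sb"`.
#' @param conf Confidence level for the bound curves.
#' @return List: `minutes` (rounded to the nearest minute),
#'   `minutes_exact`, `ci_low`, `ci_high` (`NA` when no covariance, `Inf`
#'   when a bound curve never reaches the target), `attained_hr`; or, if
#'   the target is unreachable, `minutes = NA` with the attained infimum
#'   `hr_infimum`.
#' @export
solve_reallocation <- function(model, ref,  target_hr = 0.90,
                               mode = c("mvpa_for_sb", "lipa_for_sb"),
                               conf = 0.95) {
  mode <- match.arg(mode)
  stopifnot(target_hr > 0, target_hr <= 1)
  ref <- close_composition(ref)
  total <- attr(ref, "total")
  to <- if (mode == "mvpa_for_sb") "mvpa" else "lipa"
  reall <- function(d) {
    x <- unclass(ref)
    x[to] <- x[to] + d
    x["sb"] <- x["sb"] - d
    close_composition(x, total)
  }
  curve <- function(d, what) {
    vapply(d, function(di) hazard_ratio(model, reall(di), ref,
                                        conf)[[what]], 0)
  }
  if (target_hr == 1)
    return(list(minutes = 0, minutes_exact = 0, ci_low = 0, ci_high = 0,
                attained_hr = 1))
  upper <- unclass(ref)["sb"] - 1
  solve_on <- function(what) {
    lo_val <- curve(upper, what)
    if (is.na(lo_val)) return(NA_real_)
    if (lo_val > target_hr) return(Inf)  # never reaches the target
    stats::uniroot(function(d) curve(d, what) - target_hr,
                   lower = 0, upper = upper, tol = 1e-7)$root
  }
  inf_hr <- curve(upper, "hr")
  if (inf_hr > target_hr)
    return(list(minutes = NA_real_, minutes_exact = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_,
                hr_infimum = inf_hr))
  d <- solve_on("hr")
  list(minutes = round(d),
       minutes_exact = d,
       ci_low = if (is.na(curve(1, "lo"))) NA_real_
                else round(solve_on("lo")),
       ci_high = if (is.na(curve(1, "hi"))) NA_real_
                 else round(solve_on("hi")),
       attained_hr = curve(d, "hr"))
}
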