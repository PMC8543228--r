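# Federated multivariate random-effects pooling of study fits.
#
# Each study contributes only its ilr coefficient vector and covariance
# matrix.  Studies that did not measure sleep are first lifted onto the
# 3-coordinate system with the sleep balance masked: coefficient 0 and an
# arbitrarily large variance, so their weight for that coordinate is
# negligible in the pooled estimate.

.MASKED_VAR_MIN <- 1e4  # variances at or above this mark a masked entry

#' Mask the sleep coordinate of a waking-day study
#'
#' Lifts a 2-coordinate (waking day) fit onto the 3-coordinate system:
#' the sleep balance coefficient is set to zero and given variance
#' `mask_variance` with zero cross-covariance, so the study carries
#' essentially no weight in pooling that coordinate while contributing
#' fully to the others.
#'
#' @param fit A `study_fit` with `measures_sleep = FALSE`.
#' @param mask_variance Variance assigned to the masked coordinate
#'   (default 1e6; any value above 1e4 gives indistinguishable pooled
#'   results).
#' @return A `study_fit` on coordinates (z1, z2, z3).
#' @export
mask_missing_sleep <- function(fit, mask_variance = 1e6) {
  stopifnot(inherits(fit, "study_fit"))
  if (isTRUE(fit$measures_sleep))
    stop("study '", fit$study, "' measures sleep; nothing to mask")
  if ("z1" %in% names(fit$gamma))
    stop("fit already carries a z1 coordinate")
  g <- c(z1 = 0, fit$gamma)
  V <- matrix(0, 3, 3, dimnames = list(names(g), names(g)))
  V[1, 1] <- mask_variance
  V[-1, -1] <- fit$vcov_gamma
  fit$gamma <- g
  fit$vcov_gamma <- V
  fit$masked <- TRUE
  fit
}

.theta_matrix <- function(fits) {
  nm <- names(fits[[1]]$gamma)
  for (f in fits)
    if (!identical(names(f$gamma), nm))
      stop("study fits are not on a common coordinate system; ",
           "mask waking-day studies first")
  list(theta = do.call(rbind, lapply(fits, function(f) f$gamma)),
       S = lapply(fits, function(f) f$vcov_gamma),
       names = nm,
       studies = vapply(fits, function(f) f$study, ""))
}

# REML profile log-likelihood for Psi = L L' (log-Cholesky parameters)
.reml_nll <- function(par, theta, S, pdim) {
  L <- matrix(0, pdim, pdim)
  L[lower.tri(L, diag = TRUE)] <- par
  diag(L) <- exp(diag(L))
  Psi <- L %*% t(L)
  k <- nrow(theta)
  W <- vector("list", k); sumW <- matrix(0, pdim, pdim); swt <- rep(0, pdim)
  ld <- 0
  for (i in seq_len(k)) {
    Vi <- S[[i]] + Psi
    ch <- tryCatch(chol(Vi), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ld <- ld + 2 * sum(log(diag(ch)))
    Wi <- chol2inv(ch)
    W[[i]] <- Wi
    sumW <- sumW + Wi
    swt <- swt + Wi %*% theta[i, ]
  }
  mu <- solve(sumW, swt)
  q <- 0
  for (i in seq_len(k)) {
    r <- theta[i, ] - mu
    q <- q + drop(t(r) %*% W[[i]] %*% r)
  }
  0.5 * (ld + determinant(sumW, logarithm = TRUE)$modulus + q)
}

#' Pool study fits with a multivariate random-effects model
#'
#' Estimates the pooled coefficient vector mu and between-study
#' covariance Psi under theta_i ~ N(mu, S_i + Psi), where S_i is study
#' i's within-study covariance.  The pooled estimate is the
#' inverse-variance weighted combination with weights (S_i + Psi)^-1;
#' with Psi = 0 it reduces to the fixed-effect estimate.
#'
#' @param fits List of `study_fit`s on a common coordinate system (apply
#'   [mask_missing_sleep()] first where needed).
#' @param method `"reml"` (restricted maximum likelihood, the default) or
#'   `"mm"` (per-coordinate univariate DerSimonian-Laird moments; coordinates are pooled independently).
#' @param stratum Label recorded on the result (e.g. `"all"`, `"wrist"`,
#'   `"hip"`).
#' @return A `pooled_model`: `gamma`, `vcov`, `Psi`, `k`, per-coordinate
#'   heterogeneity (`Q`, `df`, `p`, `I2`), and the input study labels.
#' @export
pool_random_effects <- function(fits, method = c("reml", "mm"),
                                stratum = "all") {
  method <- match.arg(method)
  if (inherits(fits, "study_fit")) fits <- list(fits)
  if (length(fits) == 1) {
    warning("single study: returning it unchanged with Psi = 0")
    f <- fits[[1]]
    p <- length(f$gamma)
    return(structure(
      list(gamma = f$gamma, vcov = f$vcov_gamma,
           Psi = matrix(0, p, p), k = 1L, het = NULL, stratum = stratum,
           method = method, studies = f$study),
      class = "pooled_model"))
  }
  tm <- .theta_matrix(fits)
  theta <- tm$theta; S <- tm$S; p <- ncol(theta); k <- nrow(theta)
  for (i in seq_len(k)) {
    if (any(!is.finite(S[[i]])) ||
        inherits(tryCatch(chol(S[[i]] + diag(1e-10, p)),
                          error = function(e) e), "error"))
      stop("singular or invalid vcov in study '", tm$studies[i], "'")
  }

  # per-coordinate DerSimonian-Laird tau^2 (also the REML start value)
  tau2 <- numeric(p)
  for (j in seq_len(p)) {
    v <- vapply(S, function(s) s[j, j], 0)
    use <- v < .MASKED_VAR_MIN
    if (sum(use) >= 2) {
      w <- 1 / v[use]
      th <- theta[use, j]
      mu_fe <- sum(w * th) / sum(w)
      Q <- sum(w * (th - mu_fe)^2)
      tau2[j] <- max(0, (Q - (sum(use) - 1)) /
                       (sum(w) - sum(w^2) / sum(w)))
    }
  }

  if (method == "mm") {
    # per-coordinate DerSimonian-Laird: each coefficient pooled with its
    # own univariate weights 1/(v_ij + tau2_j); coordinates decouple, so
    # a masked coordinate's study weight is exactly its (negligible)
    # inverse mask variance
    Psi <- diag(tau2, p)
    dimnames(Psi) <- list(tm$names, tm$names)
    mu <- numeric(p)
    V <- matrix(0, p, p, dimnames = list(tm$names, tm$names))
    for (j in seq_len(p)) {
      v <- vapply(S, function(s) s[j, j], 0)
      w <- 1 / (v + tau2[j])
      mu[j] <- sum(w * theta[, j]) / sum(w)
      V[j, j] <- 1 / sum(w)
    }
    names(mu) <- tm$names
    return(structure(
      list(gamma = mu, vcov = V, Psi = Psi, k = k,
           het = heterogeneity_stats(fits), stratum = stratum,
           method = method, studies = tm$studies),
      class = "pooled_model"))
  } else {
    L0 <- diag(sqrt(pmax(tau2, 1e-6)), p)
    par0 <- L0[lower.tri(L0, diag = TRUE)]
    d <- matrix(FALSE, p, p); diag(d) <- TRUE
    par0[d[lower.tri(d, diag = TRUE)]] <- log(diag(L0))
    opt <- if (length(par0) == 1) {
      stats::optim(par0, .reml_nll, theta = theta, S = S,
                   pdim = p, method = "Brent", lower = -20, upper = 5)
    } else {
      stats::optim(par0, .reml_nll, theta = theta, S = S,
                   pdim = p, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-12))
    }
    L <- matrix(0, p, p)
    L[lower.tri(L, diag = TRUE)] <- opt$par
    diag(L) <- exp(diag(L))
    Psi <- L %*% t(L)
  }
  dimnames(Psi) <- list(tm$names, tm$names)

  sumW <- matrix(0, p, p); swt <- rep(0, p)
  for (i in seq_len(k)) {
    Wi <- solve(S[[i]] + Psi)
    sumW <- sumW + Wi
    swt <- swt + Wi %*% theta[i, ]
  }
  V <- solve(sumW)
  mu <- drop(V %*% swt)
  names(mu) <- tm$names
  dimnames(V) <- list(tm$names, tm$names)
  structure(
    list(gamma = mu, vcov = V, Psi = Psi, k = k,
         het = heterogeneity_stats(fits), stratum = stratum,
         method = method, studies = tm$studies),
    class = "pooled_model")
}

#' @export
print.pooled_model <- function(x, ...) {
  cat(sprintf("<pooled_model [%s]: k=%d studies, %s>\n", x$stratum, x$k,
              x$method))
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(coef = round(x$gamma, 4), se = round(se, 4),
                    HR = round(exp(x$gamma), 3))
  print(tab)
  if (!is.null(x$het)) {
    cat("heterogeneity:\n")
    print(x$het, digits = 3)
  }
  invisible(x)
}

#' Per-coordinate heterogeneity statistics
#'
#' Cochran's Q with fixed-effect weights, its chi-square p-value on k-1
#' degrees of freedom, and I2 = max(0, (Q - df)/Q) * 100.  Masked
#' coordinates (variance >= 1e4) are excluded from their coordinate's
#' statistic.
#'
#' @param fits List of >= 2 `study_fit`s on a common coordinate system.
#' @return Data frame with one row per coordinate: `coord`, `k`, `Q`,
#'   `df`, `p`, `I2` (percent).
#' @export
heterogeneity_stats <- function(fits) {
  if (length(fits) < 2) stop("heterogeneity needs at least 2 studies")
  tm <- .theta_matrix(fits)
  out <- lapply(seq_along(tm$names), function(j) {
    v <- vapply(tm$S, function(s) s[j, j], 0)
    use <- v < .MASKED_VAR_MIN
    if (sum(use) < 2)
      return(data.frame(coord = tm$names[j], k = sum(use), Q = NA,
                        df = NA, p = NA, I2 = NA))
    w <- 1 / v[use]
    th <- tm$theta[use, j]
    mu_fe <- sum(w * th) / sum(w)
    Q <- sum(w * (th - mu_fe)^2)
    df <- sum(use) - 1
    data.frame(coord = tm$names[j], k = sum(use), Q = Q, df = df,
               p = stats::pchisq(Q, df, lower.tail = FALSE),
               I2 = max(0, (Q - df) / Q) * 100)
  })
  do.call(rbind, out)
}

#' Leave-one-out and device-stratified sensitivity pools
#'
#' Repeats the pooling k times omitting one study in turn, and once per
#' device stratum (wrist-only, hip-only).
#'
#' @param fits List of >= 3 `study_fit`s on a common coordinate system.
#' @param method Pooling method, see [pool_random_effects()].
#' @return Named list of `pooled_model`s: `"drop:<study>"` for each
#'   leave-one-out pool plus `"wrist"` and `"hip"` strata (single-study
#'   strata pass through with a warning).
#' @export
leave_one_out <- function(fits, method = "reml") {
  if (length(fits) < 3) stop("leave-one-out needs at least 3 studies")
  studies <- vapply(fits, function(f) f$study, "")
  out <- list()
  for (i in seq_along(fits)) {
    out[[paste0("drop:", studies[i])]] <-
      pool_random_effects(fits[-i], method = method,
                          stratum = paste0("drop:", studies[i]))
  }
  for (dev in c("wrist", "hip")) {
    sel <- vapply(fits, function(f) identical(f$device, dev), TRUE)
    if (any(sel))
      out[[dev]] <- pool_random_effects(fits[sel], method = method,
                                        stratum = dev)
  }
  out
}

#' Write / read a pooled model as JSON
#'
#' Full-precision serialisation with provenance (input study labels,
#' stratum, estimator settings).
#'
#' @param x A `pooled_model`.
#' @param path JSON path.
#' @return `path` (write) or a `pooled_model` (read).
#' @export
write_pooled_model <- function(x, path) {
  stopifnot(inherits(x, "pooled_model"))
  nm <- names(x$gamma)
  obj <- list(stratum = x$stratum, method = x$method, k = x$k,
              studies = x$studies, gamma_names = nm,
              gamma = as.list(.num_out(x$gamma)),
              vcov = .num_out(as.vector(t(x$vcov))),
              Psi = .num_out(as.vector(t(x$Psi))),
              het = x$het,
              software_version =
                as.character(utils::packageVersion("codasurv")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pooled_model
#' @export
read_pooled_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(o$gamma_names)
  dn <- list(o$gamma_names, o$gamma_names)
  structure(
    list(gamma = .num_in(unlist(o$gamma))[o$gamma_names],
         vcov = matrix(.num_in(o$vcov), p, p, byrow = TRUE,
                       dimnames = dn),
         Psi = matrix(.num_in(o$Psi), p, p, byrow = TRUE,
                      dimnames = dn),
         k = o$k, het = o$het, stratum = o$stratum, method = o$method,
         studies = o$studies),
    class = "pooled_model")
}

#' Assemble a pooled model from published coefficient estimates
#'
#' For effects-only analyses: build a `pooled_model` directly from
#' coefficient point estimates and (optionally) their 95% confidence
#' bounds, e.g. a published device-stratified coefficient table.  When
#' only marginal bounds are given the covariance is taken diagonal with
#' SE = (upper - lower) / (2 * 1.96); between-coordinate covariance is
#' unknown and set to zero.
#'
#' @param gamma Named coefficient vector (names among z1, z2, z3).
#' @param ci_lower,ci_upper Optional named vectors of 95% bounds.
#' @param vcov Optional full covariance matrix (overrides the bounds).
#' @param stratum Label.
#' @return A `pooled_model`.
#' @export
pooled_model_from_coefficients <- function(gamma, ci_lower = NULL,
                                           ci_upper = NULL, vcov = NULL,
                                           stratum = "external") {
  p <- length(gamma)
  nm <- names(gamma)
  if (is.null(vcov)) {
    if (!is.null(ci_lower) && !is.null(ci_upper)) {
      se <- (ci_upper[nm] - ci_lower[nm]) / (2 * stats::qnorm(0.975))
      vcov <- diag(se^2, p)
    } else {
      vcov <- matrix(NA_real_, p, p)
    }
  }
  dimnames(vcov) <- list(nm, nm)
  structure(
    list(gamma = gamma, vcov = vcov, Psi = matrix(0, p, p), k = NA,
         het = NULL, stratum = stratum, method = "external",
         studies = character(0)),
    class = "pooled_model")
}
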