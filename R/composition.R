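# Composition algebra for daily time-use data.
#
# A composition is a named numeric vector of strictly positive minutes per
# day over the parts (sleep, mvpa, lipa, sb) for a full 24-h day, or
# (mvpa, lipa, sb) for the waking day.  Only relative information matters;
# closure fixes the total.

#' Canonical part names
#'
#' Internal part order is (sleep, mvpa, lipa, sb); waking-day compositions
#' drop `sleep`.
#' @keywords internal
.parts4 <- c("sleep", "mvpa", "lipa", "sb")
.parts3 <- c("mvpa", "lipa", "sb")

#' Construct a daily time-use composition
#'
#' @param mvpa,lipa,sb Minutes/day of moderate-to-vigorous physical
#'   activity, light physical activity and sedentary behaviour.
#' @param sleep Minutes/day of sleep, or `NULL` for a waking-day
#'   (3-part) composition.
#' @param total Total minutes the parts are closed to.  Defaults to the sum
#'   of the supplied parts, i.e. the input is taken as already closed.
#' @return A named numeric vector of class `composition` with attribute
#'   `total`.
#' @examples
#' composition(mvpa = 2, lipa = 229, sb = 729)
#' composition(sleep = 437.3, mvpa = 61.8, lipa = 122.6, sb = 818.3)
#' @export
composition <- function(mvpa, lipa, sb, sleep = NULL, total = NULL) {
  x <- if (is.null(sleep)) {
    c(mvpa = mvpa, lipa = lipa, sb = sb)
  } else {
    c(sleep = sleep, mvpa = mvpa, lipa = lipa, sb = sb)
  }
  if (is.null(total)) total <- sum(x)
  close_composition(x, total)
}

#' Close a vector of parts to a fixed total
#'
#' Rescales non-negative parts so that they sum to `total` (the closure
#' operation).  Part names are preserved; unnamed input in the canonical
#' order (sleep, mvpa, lipa, sb) or (mvpa, lipa, sb) is named accordingly.
#'
#' @param parts Numeric vector of non-negative parts (3 or 4 of them).
#' @param total Positive total to close to (minutes/day).
#' @return A `composition` whose parts sum to `total`.
#' @export
close_composition <- function(parts, total = sum(parts)) {
  if (!is.numeric(parts) || length(parts) < 2)
    stop("`parts` must be a numeric vector with at least two parts")
  if (any(!is.finite(parts)) || any(parts < 0))
    stop("invalid composition: parts must be finite and non-negative")
  s <- sum(parts)
  if (s <= 0) stop("invalid composition: all parts are zero")
  if (!is.finite(total) || total <= 0) stop("`total` must be positive")
  if (is.null(names(parts))) {
    if (length(parts) == 4L) names(parts) <- .parts4
    else if (length(parts) == 3L) names(parts) <- .parts3
  }
  out <- parts * (total / s)
  structure(out, total = total, class = "composition")
}

#' @export
print.composition <- function(x, digits = 4, ...) {
  cat(sprintf("<composition: %d parts, total %.6g min>\n",
              length(x), attr(x, "total")))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' ilr contrast matrix for the movement-behaviour balance system
#'
#' Rows are the balance coordinates, columns the parts in canonical order.
#' For the 4-part day the coordinates are: z1, sleep against the geometric
#' mean of the waking behaviours; z2, MVPA against the geometric mean of
#' LIPA and SB; z3, LIPA against SB.  The waking-day system drops z1.
#' The rows are orthonormal, so z2 and z3 are identical whether computed
#' from the 4-part day or the waking subcomposition.
#'
#' @param n_parts 4 (full day) or 3 (waking day).
#' @return Matrix with `n_parts - 1` rows and `n_parts` columns.
#' @export
ilr_basis <- function(n_parts = 4) {
  if (n_parts == 4) {
    B <- rbind(
      z1 = sqrt(3 / 4) * c(1, -1 / 3, -1 / 3, -1 / 3),
      z2 = sqrt(2 / 3) * c(0, 1, -1 / 2, -1 / 2),
      z3 = sqrt(1 / 2) * c(0, 0, 1, -1))
    colnames(B) <- .parts4
  } else if (n_parts == 3) {
    B <- rbind(
      z2 = sqrt(2 / 3) * c(1, -1 / 2, -1 / 2),
      z3 = sqrt(1 / 2) * c(0, 1, -1))
    colnames(B) <- .parts3
  } else stop("`n_parts` must be 3 or 4")
  B
}

.as_part_matrix <- function(x) {
  if (inherits(x, "composition") || (is.numeric(x) && is.null(dim(x)))) {
    x <- matrix(unclass(x), nrow = 1, dimnames = list(NULL, names(x)))
  } else if (!is.matrix(x)) {
    x <- as.matrix(as.data.frame(x))
  }
  nm <- colnames(x)
  if (is.null(nm)) {
    if (ncol(x) == 4L) colnames(x) <- .parts4
    else if (ncol(x) == 3L) colnames(x) <- .parts3
    else stop("compositions must have 3 or 4 parts")
  } else {
    nm <- tolower(nm)
    colnames(x) <- nm
    want <- if ("sleep" %in% nm) .parts4 else .parts3
    if (!all(want %in% nm))
      stop("composition columns must be named ",
           paste(want, collapse = ", "))
    x <- x[, want, drop = FALSE]
  }
  x
}

#' Forward ilr transform
#'
#' Maps compositions to the balance coordinates (z1, z2, z3) of the
#' movement-behaviour system; waking-day (3-part) input yields (z2, z3).
#' The transform is invariant to the composition's total, so minutes,
#' hours or proportions give identical coordinates.
#'
#' @param x A `composition`, a named numeric vector, or a matrix /
#'   data frame with one composition per row.
#' @return A named numeric vector of coordinates, or a matrix with one row
#'   per input row.
#' @examples
#' ilr_forward(composition(mvpa = 2, lipa = 229, sb = 729))
#' @export
ilr_forward <- function(x) {
  m <- .as_part_matrix(x)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("ilr requires strictly positive parts; impute zeros first ",
         "(see `impute_zeros()`)")
  B <- ilr_basis(ncol(m))
  z <- log(m) %*% t(B)
  if (nrow(z) == 1L && (is.null(dim(x)) || inherits(x, "composition")))
    return(drop(z)[rownames(B)])
  colnames(z) <- rownames(B)
  z
}

#' Inverse ilr transform
#'
#' Maps balance coordinates back to a composition closed to `total`.
#' `ilr_forward(ilr_inverse(z))` recovers `z` to numerical precision.
#'
#' @param z Numeric vector of coordinates named (z1, z2, z3) or (z2, z3),
#'   or a matrix with one coordinate vector per row.
#' @param total Total minutes of the returned composition.
#' @return A `composition`, or a matrix of parts for matrix input.
#' @export
ilr_inverse <- function(z, total = 1440) {
  single <- is.null(dim(z))
  zm <- if (single) matrix(z, nrow = 1, dimnames = list(NULL, names(z)))
        else as.matrix(z)
  if (any(!is.finite(zm))) stop("ilr coordinates must be finite")
  B <- ilr_basis(ncol(zm) + 1L)
  if (!is.null(colnames(zm))) {
    if (!all(colnames(zm) %in% rownames(B)))
      stop("coordinate names must be among ",
           paste(rownames(B), collapse = ", "))
    zm <- zm[, rownames(B), drop = FALSE]
  }
  e <- exp(zm %*% B)
  parts <- e * (total / rowSums(e))
  colnames(parts) <- colnames(B)
  if (single) close_composition(drop(parts), total) else parts
}

#' Compositional geometric centre of a set of compositions
#'
#' The part-wise geometric mean, closed to the common total: the
#' compositional analogue of the sample mean, and the natural summary for
#' a cohort's average daily time-use pattern.
#'
#' @param x Matrix or data frame of compositions (one per row), all parts
#'   strictly positive.
#' @param total Total to close the centre to; defaults to the mean row sum.
#' @return A `composition`.
#' @export
geometric_center <- function(x, total = NULL) {
  m <- .as_part_matrix(x)
  if (any(m <= 0) || any(!is.finite(m)))
    stop("geometric centre requires strictly positive parts")
  if (is.null(total)) total <- mean(rowSums(m))
  g <- exp(colMeans(log(m)))
  close_composition(g, total)
}
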