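# Classical alignment-tensor (Saupe) SVD fitting: the comparison baseline
# against which the tensor-free restrained dynamics is judged.

#' Direction-cosine coefficient matrix
#'
#' Row i encodes `D_i = D_stat_i * (coefficients . saupe)` with the Saupe
#' components ordered (S_zz, S_xx - S_yy, S_xy, S_xz, S_yz):
#' `c = ((3uz^2 - 1)/2, (ux^2 - uy^2)/2, 2 ux uy, 2 ux uz, 2 uy uz)`.
#' A vector along z couples only to S_zz with coefficient 1.
#'
#' @param structure `conformation` or n x 3 coordinate matrix.
#' @param rdc tibble with columns `i`, `j` (atom indices) and `d_stat`
#'   (static splitting, Hz; `NA` uses the one-bond default).
#' @return n_rdc x 5 matrix of `D_stat`-scaled coefficients (Hz).
#' @export
direction_cosine_matrix <- function(structure, rdc) {
  xyz <- as_xyz(structure)
  A <- matrix(0, nrow(rdc), 5)
  for (r in seq_len(nrow(rdc))) {
    d <- xyz[rdc$i[r], ] - xyz[rdc$j[r], ]
    rr <- sqrt(sum(d^2))
    if (rr < 1e-8) stop("zero-length internuclear vector in RDC ", r)
    u <- d / rr
    ds <- if (!("d_stat" %in% names(rdc)) || is.na(rdc$d_stat[r]))
      d_stat_default("ch_sp3") else rdc$d_stat[r]
    A[r, ] <- ds * c((3 * u[3]^2 - 1) / 2, (u[1]^2 - u[2]^2) / 2,
                     2 * u[1] * u[2], 2 * u[1] * u[3], 2 * u[2] * u[3])
  }
  A
}

saupe_vec_to_matrix <- function(s) {
  szz <- s[1]; sxx <- (s[2] - szz) / 2; syy <- -(s[2] + szz) / 2
  matrix(c(sxx, s[3], s[4],
           s[3], syy, s[5],
           s[4], s[5], szz), 3, 3, byrow = TRUE)
}

#' Fit a Saupe alignment tensor by SVD
#'
#' Least-squares solution of the linear RDC equations for the 5
#' independent Saupe components via singular-value decomposition;
#' unweighted by default, or weighted by 1/error.
#'
#' @param structure `conformation` or coordinate matrix.
#' @param rdc tibble with `i`, `j`, `d_exp`, `error` (and optional
#'   `d_stat`, `id`).
#' @param weighted divide each row by its experimental error.
#' @return object of class `saupe_fit`: Saupe components and 3 x 3 matrix,
#'   back-calculated RDCs, Q, quality criteria, singular values and
#'   condition number.
#' @export
fit_saupe <- function(structure, rdc, weighted = FALSE) {
  n <- nrow(rdc)
  if (n < 5) {
    stop("underdetermined: ", n, " RDCs for 5 Saupe components (need >= 5)")
  }
  A <- direction_cosine_matrix(structure, rdc)
  fit <- fit_saupe_on_matrix(A, rdc, weighted)
  if (any(fit$singular_values < 1e-10 * max(fit$singular_values))) {
    fit$warning <- "rank-deficient coefficient matrix: Saupe tensor underdetermined"
    warning(fit$warning)
  }
  fit
}

#' Multi-conformer Saupe fit with a common tensor
#'
#' Population-weighted average of the per-conformer coefficient rows under
#' one shared alignment tensor, scanned over a simplex grid of populations
#' (default step 0.05); the population vector with the lowest chi-squared
#' wins.
#'
#' @param structures list of conformations/coordinate matrices with
#'   consistent atom ordering.
#' @param rdc as in [fit_saupe()].
#' @param step simplex grid resolution.
#' @param weighted see [fit_saupe()].
#' @return the best `saupe_fit`, with `populations` set and the full
#'   `population_grid` search attached.
#' @export
multi_conformer_fit <- function(structures, rdc, step = 0.05,
                                weighted = FALSE) {
  m <- length(structures)
  if (m < 2) stop("need at least two conformers")
  dims <- vapply(structures, function(s) nrow(as_xyz(s)), integer(1))
  if (length(unique(dims)) != 1) stop("inconsistent atom sets across conformers")
  mats <- lapply(structures, direction_cosine_matrix, rdc = rdc)
  grid <- simplex_grid(m, step)
  n <- nrow(rdc)
  w <- if (weighted) 1 / rdc$error else rep(1, n)
  b <- rdc$d_exp
  best <- NULL; best_chi <- Inf; chis <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- grid[g, ]
    A <- Reduce(`+`, Map(function(M, pp) pp * M, mats, p))
    sv <- svd(A * w)
    dinv <- ifelse(sv$d < 1e-10 * max(sv$d), 0, 1 / sv$d)
    s <- sv$v %*% (dinv * (t(sv$u) %*% (b * w)))
    back <- as.vector(A %*% s)
    chi <- sum(((back - b) / rdc$error)^2)
    chis[g] <- chi
    if (chi < best_chi) { best_chi <- chi; best <- list(p = p, A = A) }
  }
  fitlike <- fit_saupe_on_matrix(best$A, rdc, weighted)
  fitlike$populations <- best$p
  fitlike$population_grid <- tibble::tibble(
    population = lapply(seq_len(nrow(grid)), function(i) grid[i, ]),
    chisq = chis)
  fitlike
}

fit_saupe_on_matrix <- function(A, rdc, weighted) {
  n <- nrow(rdc)
  b <- rdc$d_exp
  w <- if (weighted) 1 / rdc$error else rep(1, n)
  sv <- svd(A * w)
  dinv <- ifelse(sv$d < 1e-10 * max(sv$d), 0, 1 / sv$d)
  s <- sv$v %*% (dinv * (t(sv$u) %*% (b * w)))
  back <- as.vector(A %*% s)
  ids <- if ("id" %in% names(rdc)) rdc$id else as.character(seq_len(n))
  qc <- chi2_quality(back, b, rdc$error)
  fd <- fidelity(back, b, rdc$error, ids)
  structure(list(
    saupe = as.vector(s), saupe_matrix = saupe_vec_to_matrix(as.vector(s)),
    back_calculated = back, observed = b, error = rdc$error, id = ids,
    q = q_factor(back, b), chisq = qc$chisq, quality = qc$quality,
    inv_chisq_min = outlier_criterion(back, b, rdc$error),
    fidelity = fd$fidelity, outliers = fd$outliers,
    singular_values = sv$d, condition = max(sv$d) / max(min(sv$d), 1e-300),
    populations = NULL, warning = NULL, weighted = weighted),
    class = "saupe_fit")
}

simplex_grid <- function(m, step) {
  k <- round(1 / step)
  combos <- compositions(k, m)
  combos / k
}

# all m-part compositions of k (rows sum to k)
compositions <- function(k, m) {
  if (m == 1) return(matrix(k, 1, 1))
  out <- list()
  for (first in 0:k) {
    rest <- compositions(k - first, m - 1)
    out[[length(out) + 1]] <- cbind(first, rest)
  }
  res <- do.call(rbind, out)
  dimnames(res) <- NULL
  res
}

#' @export
print.saupe_fit <- function(x, ...) {
  cat("<saupe_fit> n =", length(x$observed),
      " Q =", signif(x$q, 3),
      " n/chi2 =", signif(x$quality, 3),
      " 1/chi2_min =", signif(x$inv_chisq_min, 3),
      " F =", signif(x$fidelity, 3), "\n")
  if (!is.null(x$populations)) {
    cat("  populations:", paste(signif(x$populations, 3), collapse = " / "), "\n")
  }
  invisible(x)
}

#' @method tidy saupe_fit
#' @export
tidy.saupe_fit <- function(x, ...) {
  tibble::tibble(id = x$id, observed = x$observed,
                 back_calculated = x$back_calculated, error = x$error,
                 outlier = x$id %in% x$outliers)
}

#' @method glance saupe_fit
#' @export
glance.saupe_fit <- function(x, ...) {
  tibble::tibble(n = length(x$observed), q = x$q, chisq = x$chisq,
                 quality = x$quality, inv_chisq_min = x$inv_chisq_min,
                 fidelity = x$fidelity, condition = x$condition)
}

#' Observed vs back-calculated RDC plot
#'
#' @param object a `saupe_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot saupe_fit
#' @export
autoplot.saupe_fit <- function(object, ...) {
  d <- tidy.saupe_fit(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed,
                                  y = .data$back_calculated,
                                  colour = .data$outlier)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$back_calculated - .data$error,
                                        ymax = .data$back_calculated + .data$error),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "observed RDC (Hz)", y = "back-calculated RDC (Hz)",
                  subtitle = sprintf("Q = %.3g, n/chi2 = %.3g",
                                     object$q, object$quality))
}
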