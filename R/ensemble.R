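# Torsion statistics, rotamer populations and complex dihedral PCA.

#' Torsion-angle series over a trajectory
#'
#' @param trajectory an `mdoc_trajectory`, `reference_ensemble`, or list of
#'   coordinate matrices.
#' @param idx four 1-based atom indices.
#' @return signed dihedral angles in degrees, one per frame.
#' @export
torsion_series <- function(trajectory, idx) {
  frames <- trajectory_frames(trajectory)
  vapply(frames, dihedral_angle, numeric(1), idx = idx)
}

trajectory_frames <- function(trajectory) {
  if (inherits(trajectory, "mdoc_trajectory")) return(trajectory$coords)
  if (inherits(trajectory, "reference_ensemble")) return(trajectory$coords)
  if (is.list(trajectory)) return(trajectory)
  stop("cannot extract frames from ", class(trajectory)[1])
}

#' Rotamer populations of a torsion-angle series
#'
#' Three-state binning matching the usual trans/gauche nomenclature:
#' trans for |omega| >= 120 deg, gauche(+) for 0 < omega < 120 deg,
#' gauche(-) for -120 < omega <= 0 deg.
#'
#' @param angles numeric vector of angles, degrees in (-180, 180].
#' @param bin_width histogram bin width, degrees.
#' @return object of class `rotamer_stats` with `fractions`, a histogram
#'   tibble and the raw series.
#' @export
rotamer_populations <- function(angles, bin_width = 5) {
  if (!length(angles)) stop("empty angle series")
  state <- rotamer_state(angles)
  fr <- c(trans = mean(state == "trans"),
          `gauche-` = mean(state == "gauche-"),
          `gauche+` = mean(state == "gauche+"))
  breaks <- seq(-180, 180, by = bin_width)
  h <- hist(angles, breaks = breaks, plot = FALSE)
  structure(list(
    fractions = fr,
    histogram = tibble::tibble(mid = h$mids, count = h$counts,
                               density = h$density),
    series = angles),
    class = "rotamer_stats")
}

rotamer_state <- function(angles) {
  ifelse(abs(angles) >= 120, "trans",
         ifelse(angles > 0, "gauche+", "gauche-"))
}

#' @export
print.rotamer_stats <- function(x, ...) {
  cat("<rotamer_stats> n =", length(x$series), "\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' @method tidy rotamer_stats
#' @export
tidy.rotamer_stats <- function(x, ...) {
  tibble::tibble(state = names(x$fractions), fraction = unname(x$fractions))
}

#' Torsion histogram plot
#'
#' @param object a `rotamer_stats`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot rotamer_stats
#' @export
autoplot.rotamer_stats <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_col(width = diff(object$histogram$mid[1:2])) +
    ggplot2::geom_vline(xintercept = c(-120, 0, 120), linetype = 3) +
    ggplot2::labs(x = "torsion angle (deg)", y = "density")
}

#' Complex dihedral principal component analysis
#'
#' Each dihedral phi is mapped to the unit complex number exp(i phi) so
#' circular statistics are respected; the Hermitian covariance of the
#' mean-centred variables is diagonalised. Per-component dihedral
#' contributions are the moduli of the (unit-norm) eigenvector entries, and
#' each snapshot projects onto component n as a single angle
#' `theta_n = Arg(sum_j conj(v_nj) exp(i phi_j))`.
#'
#' @param angles snapshots x dihedrals matrix, degrees.
#' @return object of class `dpca`: `values` (eigenvalues, descending),
#'   `vectors` (complex), `contributions` (dihedrals x components moduli),
#'   `theta` (snapshots x components projection angles, degrees).
#' @export
dpca <- function(angles) {
  angles <- as.matrix(angles)
  if (nrow(angles) < 2) stop("need at least two snapshots")
  z <- exp(1i * deg2rad(angles))
  zc <- sweep(z, 2, colMeans(z))
  C <- crossprod(Conj(zc), zc) / (nrow(z) - 1)   # Hermitian covariance
  total_var <- sum(Re(diag(C)))
  if (total_var < 1e-12) stop("zero covariance: all dihedrals are constant")
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(Re(e$values), 0)
  vecs <- e$vectors
  proj <- z %*% Conj(vecs)
  theta <- rad2deg(Arg(proj))
  dn <- colnames(angles) %||% paste0("phi", seq_len(ncol(angles)))
  structure(list(values = vals, vectors = vecs,
                 contributions = Mod(vecs),
                 theta = theta, dihedral_names = dn,
                 total_variance = total_var),
            class = "dpca")
}

#' @export
print.dpca <- function(x, ...) {
  cat("<dpca>", length(x$values), "dihedrals,",
      nrow(x$theta), "snapshots; leading eigenvalues:",
      paste(signif(utils::head(x$values, 3), 3), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy dpca
#' @export
tidy.dpca <- function(x, ...) {
  nc <- length(x$values)
  tibble::tibble(
    component = rep(seq_len(nc), each = nc),
    dihedral = rep(x$dihedral_names, times = nc),
    contribution = as.vector(x$contributions),
    eigenvalue = rep(x$values, each = nc))
}

#' @method glance dpca
#' @export
glance.dpca <- function(x, ...) {
  tibble::tibble(n_dihedrals = length(x$values),
                 n_snapshots = nrow(x$theta),
                 total_variance = x$total_variance,
                 var_pc1 = x$values[1] / x$total_variance,
                 var_pc2 = if (length(x$values) > 1)
                   x$values[2] / x$total_variance else NA_real_)
}

#' Dihedral landscape of the first two principal components
#'
#' Scatter of the per-snapshot projection angles (theta_1, theta_2); for a
#' single component, a theta_1 histogram.
#'
#' @param object a `dpca`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot dpca
#' @export
autoplot.dpca <- function(object, ...) {
  if (ncol(object$theta) >= 2) {
    d <- tibble::tibble(theta1 = object$theta[, 1], theta2 = object$theta[, 2])
    ggplot2::ggplot(d, ggplot2::aes(x = .data$theta1, y = .data$theta2)) +
      ggplot2::geom_point(alpha = 0.3, size = 0.5) +
      ggplot2::coord_cartesian(xlim = c(-180, 180), ylim = c(-180, 180)) +
      ggplot2::labs(x = expression(theta[1] * " (deg)"),
                    y = expression(theta[2] * " (deg)"))
  } else {
    d <- tibble::tibble(theta1 = object$theta[, 1])
    ggplot2::ggplot(d, ggplot2::aes(x = .data$theta1)) +
      ggplot2::geom_histogram(binwidth = 5) +
      ggplot2::labs(x = expression(theta[1] * " (deg)"))
  }
}
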