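#' Build a validated molecular system
#'
#' Assembles the molecular topology and lightweight classical force field
#' used by the MDOC engine: harmonic bonds and angles, cosine torsions,
#' Lennard-Jones plus fixed-charge Coulomb nonbonded terms with 1-2/1-3
#' exclusions and scaled 1-4 interactions. Angle and torsion lists are
#' derived from the bond graph when not supplied (paths of length 2 and 3),
#' using the parameters in `defaults`.
#'
#' @param topology a list with components:
#'   \describe{
#'     \item{atoms}{tibble/data frame: `name`, `element`, `mass` (u),
#'       `charge` (e), `sigma` (A), `epsilon` (kJ/mol).}
#'     \item{bonds}{`i`, `j` (1-based), `r0` (A), `k` (kJ mol^-1 A^-2,
#'       for E = k/2 (r - r0)^2).}
#'     \item{angles}{optional: `i`, `j`, `k`, `theta0` (deg), `kth`
#'       (kJ mol^-1 rad^-2).}
#'     \item{torsions}{optional: `i`, `j`, `k`, `l`, `n` (periodicity),
#'       `phase` (deg), `v` (barrier kJ/mol, E = v/2 (1 + cos(n phi - phase))).}
#'   }
#' @param defaults parameters for auto-derived angle/torsion terms.
#' @param scale14 scaling of 1-4 Lennard-Jones and Coulomb interactions.
#' @param cutoff nonbonded cutoff, A.
#' @return object of class `molecular_system`.
#' @export
build_system <- function(topology,
                         defaults = list(theta0 = 109.47, kth = 320,
                                         tor_n = 3, tor_phase = 0, tor_v = 5),
                         scale14 = 0.5, cutoff = 12) {
  atoms <- tibble::as_tibble(topology$atoms)
  bonds <- tibble::as_tibble(topology$bonds)
  n <- nrow(atoms)
  if (n < 2) stop("system needs at least two atoms")
  if (any(atoms$mass <= 0)) {
    stop("non-positive mass for atom(s): ",
         paste(which(atoms$mass <= 0), collapse = ", "))
  }
  check_idx <- function(df, cols, what) {
    m <- as.matrix(df[cols])
    bad <- which(rowSums(m < 1 | m > n) > 0)
    if (length(bad)) stop("out-of-range atom index in ", what, " record ", bad[1])
    bad <- which(apply(m, 1, anyDuplicated) > 0)
    if (length(bad)) stop("repeated atom index in ", what, " record ", bad[1],
                          " (self-reference is invalid)")
    invisible(m)
  }
  check_idx(bonds, c("i", "j"), "bond")
  key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  if (anyDuplicated(key)) {
    stop("duplicate bond record ", which(duplicated(key))[1])
  }

  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$i[b]]] <- c(adj[[bonds$i[b]]], bonds$j[b])
    adj[[bonds$j[b]]] <- c(adj[[bonds$j[b]]], bonds$i[b])
  }
  # connectivity check (BFS from atom 1)
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  if (!all(seen)) {
    stop("disconnected atoms: ", paste(which(!seen), collapse = ", "))
  }

  angles <- topology$angles
  if (is.null(angles)) {
    out <- list()
    for (j in seq_len(n)) {
      nb <- sort(adj[[j]])
      if (length(nb) >= 2) {
        cmb <- utils::combn(nb, 2)
        out[[length(out) + 1]] <- tibble::tibble(
          i = cmb[1, ], j = j, k = cmb[2, ],
          theta0 = defaults$theta0, kth = defaults$kth)
      }
    }
    angles <- if (length(out)) dplyr::bind_rows(out) else
      tibble::tibble(i = integer(), j = integer(), k = integer(),
                     theta0 = numeric(), kth = numeric())
  } else {
    angles <- tibble::as_tibble(angles)
    check_idx(angles, c("i", "j", "k"), "angle")
  }

  torsions <- topology$torsions
  if (is.null(torsions) || nrow(tibble::as_tibble(torsions)) == 0) {
    out <- list()
    for (b in seq_len(nrow(bonds))) {
      j <- bonds$i[b]; k <- bonds$j[b]
      for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j)) {
        if (i != l) {
          out[[length(out) + 1]] <- tibble::tibble(
            i = i, j = j, k = k, l = l,
            n = defaults$tor_n, phase = defaults$tor_phase, v = defaults$tor_v)
        }
      }
    }
    torsions <- if (length(out)) dplyr::bind_rows(out) else
      tibble::tibble(i = integer(), j = integer(), k = integer(), l = integer(),
                     n = integer(), phase = numeric(), v = numeric())
  } else {
    torsions <- tibble::as_tibble(torsions)
    check_idx(torsions, c("i", "j", "k", "l"), "torsion")
  }

  # graph distances up to 3 bonds -> exclusions and 1-4 scaling
  dist3 <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    d <- rep(Inf, n); d[i] <- 0; frontier <- i
    for (lev in 1:3) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[d[nxt] == Inf]
      d[nxt] <- lev
      frontier <- nxt
      if (!length(frontier)) break
    }
    dist3[i, ] <- d
  }
  pi_ <- integer(0); pj_ <- integer(0); ps_ <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (dist3[i, j] <= 2) next
    pi_ <- c(pi_, i); pj_ <- c(pj_, j)
    ps_ <- c(ps_, if (dist3[i, j] == 3) scale14 else 1)
  }
  pairs <- tibble::tibble(i = pi_, j = pj_, scale = ps_)

  sys <- structure(list(atoms = atoms, bonds = bonds, angles = angles,
                        torsions = torsions, pairs = pairs,
                        scale14 = scale14, cutoff = cutoff),
                   class = "molecular_system")
  sys$compiled <- compile_system(sys)
  sys
}

# flatten to the 0-based arrays the C++ core consumes
compile_system <- function(sys) {
  a <- sys$atoms
  prs <- sys$pairs
  sig <- (a$sigma[prs$i] + a$sigma[prs$j]) / 2
  eps <- sqrt(a$epsilon[prs$i] * a$epsilon[prs$j])
  qq <- .coulomb_const * a$charge[prs$i] * a$charge[prs$j]
  list(
    mass = as.numeric(a$mass),
    bonds = cbind(sys$bonds$i, sys$bonds$j) - 1L,
    bond_r0 = as.numeric(sys$bonds$r0), bond_k = as.numeric(sys$bonds$k),
    angles = cbind(sys$angles$i, sys$angles$j, sys$angles$k) - 1L,
    ang_th0 = deg2rad(as.numeric(sys$angles$theta0)),
    ang_k = as.numeric(sys$angles$kth),
    tors = cbind(sys$torsions$i, sys$torsions$j, sys$torsions$k, sys$torsions$l) - 1L,
    tor_n = as.integer(sys$torsions$n),
    tor_phase = deg2rad(as.numeric(sys$torsions$phase)),
    tor_v = as.numeric(sys$torsions$v),
    pairs = cbind(prs$i, prs$j) - 1L,
    pr_sig = sig, pr_eps = eps, pr_qq = qq, pr_scale = as.numeric(prs$scale),
    cutoff = sys$cutoff
  )
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("<molecular_system> ", nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds, ",
      nrow(x$angles), " angles, ", nrow(x$torsions), " torsions\n", sep = "")
  invisible(x)
}

#' Create a conformation
#'
#' A conformation bundles a time stamp (ps), Cartesian coordinates (A) and
#' velocities (A/ps), one row per atom.
#'
#' @param xyz n x 3 coordinate matrix.
#' @param vel n x 3 velocity matrix (zero if omitted).
#' @param time time stamp, ps.
#' @return object of class `conformation`.
#' @export
conformation <- function(xyz, vel = NULL, time = 0) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3)
  if (is.null(vel)) vel <- matrix(0, nrow(xyz), 3)
  stopifnot(identical(dim(vel), dim(xyz)))
  structure(list(time = time, xyz = xyz, vel = vel), class = "conformation")
}

#' Force-field energy and forces
#'
#' Evaluates the classical energy (bond + angle + torsion + Lennard-Jones +
#' Coulomb, kJ/mol) and its exact negative gradient (kJ mol^-1 A^-1, one row
#' per atom).
#'
#' @param system a `molecular_system`.
#' @param conf a `conformation` or coordinate matrix.
#' @return list with `energy`, `forces` (n x 3) and per-term `terms`.
#' @export
ff_energy_forces <- function(system, conf) {
  x <- as_xyz(conf)
  stopifnot(nrow(x) == nrow(system$atoms))
  cpp_ff(x, system$compiled)
}
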