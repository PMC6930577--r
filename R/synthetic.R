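# Synthetic acceptance surface: toy rotor molecules, reference ensembles
# with known rotamer populations, and noisy pseudo-experimental RDC/NOE/3J
# tables generated from them under an imposed Saupe tensor.

#' Build a toy molecule
#'
#' `"single-rotor"`: a 20-atom 2,3-dimethylbutane-like molecule — two
#' semi-rigid fragments (each a methine carbon carrying two methyl groups
#' and one proton) joined by one soft central C-C torsion populating
#' trans/gauche states (3-fold barrier 6 kJ/mol; methyl torsions are kept
#' stiff at 18 kJ/mol so the rotor is the single soft degree of freedom).
#' `"chain"`: a pentane-like chain with two soft skeletal torsions.
#'
#' @param kind toy-molecule kind.
#' @return list with `system` (a `molecular_system`), `conformation`
#'   (clash-free starting geometry, trans rotor), `info` (rotor
#'   definition, moving-fragment atoms, methyl groups, methine CH pairs,
#'   proton list) and `datasets` (value-free constraint definitions used by
#'   [synthesize_constraints()]).
#' @export
make_toy_molecule <- function(kind = c("single-rotor", "chain")) {
  kind <- match.arg(kind)
  switch(kind, `single-rotor` = toy_single_rotor(), chain = toy_chain())
}

toy_elements <- function(el) {
  tibble::tibble(
    element = el,
    mass = ifelse(el == "C", 12.011, 1.008),
    sigma = ifelse(el == "C", 3.40, 2.50),
    epsilon = ifelse(el == "C", 0.36, 0.08))
}

# angle parameters by element composition at the vertex
toy_angle_params <- function(angles, el) {
  comp <- paste0(el[angles$i], el[angles$j], el[angles$k])
  ccc <- comp == "CCC"
  hch <- substr(comp, 1, 1) == "H" & substr(comp, 3, 3) == "H"
  angles$theta0 <- ifelse(ccc, 111, ifelse(hch, 108.5, 110))
  angles$kth <- ifelse(ccc, 335, ifelse(hch, 290, 320))
  angles
}

toy_single_rotor <- function() {
  el <- c(rep("C", 6), rep("H", 14))
  atoms <- toy_elements(el)
  atoms$name <- c("C1", "C2", "C3", "C4", "C5", "C6", "H2", "H3",
                  paste0("H1", letters[1:3]), paste0("H5", letters[1:3]),
                  paste0("H4", letters[1:3]), paste0("H6", letters[1:3]))
  atoms$charge <- ifelse(el == "H", 0.03, NA)
  atoms$charge[1:6] <- c(-0.09, -0.03, -0.03, -0.09, -0.09, -0.09)

  bonds <- tibble::tibble(
    i = c(1, 2, 3, 2, 3, 2, 3, 1, 1, 1, 5, 5, 5, 4, 4, 4, 6, 6, 6),
    j = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20),
    r0 = c(rep(1.54, 5), rep(1.09, 14)),
    k = c(rep(2600, 5), rep(2900, 14)))

  torsions <- tibble::tibble(
    i = c(1, 3, 3, 2, 2), j = c(2, 2, 2, 3, 3), k = c(3, 1, 5, 4, 6),
    l = c(4, 9, 12, 15, 18),
    n = 3, phase = 0, v = c(6, 18, 18, 18, 18))

  xyz <- matrix(NA_real_, 20, 3)
  xyz[2, ] <- c(0, 0, 0)
  xyz[3, ] <- c(1.54, 0, 0)
  xyz[1, ] <- c(1.54 * cos(deg2rad(111)), 1.54 * sin(deg2rad(111)), 0)
  xyz[5, ] <- place_atom(xyz[1, ], xyz[3, ], xyz[2, ], 1.54, 111, 120)
  xyz[7, ] <- place_atom(xyz[1, ], xyz[3, ], xyz[2, ], 1.09, 109, -120)
  xyz[4, ] <- place_atom(xyz[1, ], xyz[2, ], xyz[3, ], 1.54, 111, 180)
  xyz[6, ] <- place_atom(xyz[1, ], xyz[2, ], xyz[3, ], 1.54, 111, -60)
  xyz[8, ] <- place_atom(xyz[1, ], xyz[2, ], xyz[3, ], 1.09, 109, 60)
  put_methyl <- function(xyz, ref, c2, cm, hs) {
    for (q in 1:3) {
      xyz[hs[q], ] <- place_atom(xyz[ref, ], xyz[c2, ], xyz[cm, ], 1.09, 110,
                                 c(180, 60, -60)[q])
    }
    xyz
  }
  xyz <- put_methyl(xyz, 3, 2, 1, 9:11)
  xyz <- put_methyl(xyz, 3, 2, 5, 12:14)
  xyz <- put_methyl(xyz, 2, 3, 4, 15:17)
  xyz <- put_methyl(xyz, 2, 3, 6, 18:20)

  system <- build_system(list(atoms = atoms, bonds = bonds,
                              torsions = torsions))
  system <- rebuild_with_angle_params(system, atoms, bonds, torsions, el)

  info <- list(
    kind = "single-rotor",
    rotor = c(1, 2, 3, 4),
    moving = c(4, 6, 8, 15:20),
    methyls = list(c(1, 9, 10, 11), c(5, 12, 13, 14),
                   c(4, 15, 16, 17), c(6, 18, 19, 20)),
    methine = list(c(2, 7), c(3, 8)),
    protons = 7:20)

  datasets <- toy_single_rotor_datasets(atoms$name)
  list(system = system, conformation = conformation(xyz), info = info,
       datasets = datasets)
}

rebuild_with_angle_params <- function(system, atoms, bonds, torsions, el) {
  angles <- toy_angle_params(system$angles, el)
  build_system(list(atoms = atoms, bonds = bonds, angles = angles,
                    torsions = torsions))
}

# value-free constraint definitions shaped like the diketone dataset mix
# (one-bond CH, long-range HH, NOE, 3J)
toy_single_rotor_datasets <- function(names) {
  rdc <- dplyr::bind_rows(
    tibble::tibble(id = c("D_C2H2", "D_C3H3"), class = "one-bond",
                   i = c(2L, 3L), j = c(7L, 8L),
                   h2 = NA_integer_, h3 = NA_integer_),
    tibble::tibble(id = c("D_Me1", "D_Me5", "D_Me4", "D_Me6"),
                   class = "methyl",
                   i = c(1L, 5L, 4L, 6L), j = c(9L, 12L, 15L, 18L),
                   h2 = c(10L, 13L, 16L, 19L), h3 = c(11L, 14L, 17L, 20L)),
    tibble::tibble(
      id = c("D_H2H3", "D_H2H4a", "D_H2H6a", "D_H3H1a",
             "D_H3H5a", "D_H1aH4a", "D_H5aH6a", "D_H1aH6a"),
      class = "long-range",
      i = c(7L, 7L, 7L, 8L, 8L, 9L, 12L, 9L),
      j = c(8L, 15L, 18L, 9L, 12L, 15L, 18L, 18L),
      h2 = NA_integer_, h3 = NA_integer_))
  noe <- tibble::tibble(
    id = c("N_H2H3", "N_H2Me4", "N_H3Me1", "N_H2H6a",
           "N_H3H5a", "N_H1aH4a", "N_H5aH6a"),
    i = c(7L, 7L, 8L, 7L, 8L, 9L, 12L),
    j = c(8L, 15L, 9L, 18L, 12L, 15L, 18L),
    h2 = c(NA, 16L, 10L, NA, NA, NA, NA),
    h3 = c(NA, 17L, 11L, NA, NA, NA, NA))
  jt <- tibble::tibble(
    id = c("J_H2H3", "J_Me1H2", "J_Me5H2", "J_Me4H3", "J_Me6H3"),
    i = c(7L, 9L, 12L, 15L, 18L),
    j = c(2L, 1L, 5L, 4L, 6L),
    k = c(3L, 2L, 2L, 3L, 3L),
    l = c(8L, 7L, 7L, 8L, 8L),
    chi = c("0.4,0.4,0.4,0.4", "0.4,0.4", "0.4,0.4", "0.4,0.4", "0.4,0.4"),
    xi = c("1,-1,-1,1", "1,-1", "1,-1", "1,-1", "1,-1"),
    param_set = "hla2")
  list(rdc = rdc, noe = noe, j = jt)
}

toy_chain <- function() {
  el <- c(rep("C", 5), rep("H", 12))
  atoms <- toy_elements(el)
  atoms$name <- c(paste0("C", 1:5),
                  paste0("H1", letters[1:3]), paste0("H2", letters[1:2]),
                  paste0("H3", letters[1:2]), paste0("H4", letters[1:2]),
                  paste0("H5", letters[1:3]))
  atoms$charge <- ifelse(el == "H", 0.03, NA)
  atoms$charge[1:5] <- c(-0.09, -0.06, -0.06, -0.06, -0.09)
  bonds <- tibble::tibble(
    i = c(1, 2, 3, 4, 1, 1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 5),
    j = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17),
    r0 = c(rep(1.54, 4), rep(1.09, 12)),
    k = c(rep(2600, 4), rep(2900, 12)))
  torsions <- tibble::tibble(
    i = c(1, 2, 3, 3), j = c(2, 3, 2, 4), k = c(3, 4, 1, 5),
    l = c(4, 5, 6, 15),
    n = 3, phase = 0, v = c(6, 6, 18, 18))
  xyz <- matrix(NA_real_, 17, 3)
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(1.54, 0, 0)
  xyz[3, ] <- place_atom(c(0, 1, 0), xyz[1, ], xyz[2, ], 1.54, 111, 0)
  xyz[4, ] <- place_atom(xyz[1, ], xyz[2, ], xyz[3, ], 1.54, 111, 180)
  xyz[5, ] <- place_atom(xyz[2, ], xyz[3, ], xyz[4, ], 1.54, 111, 180)
  for (q in 1:3) {
    xyz[5 + q, ] <- place_atom(xyz[3, ], xyz[2, ], xyz[1, ], 1.09, 110,
                               c(180, 60, -60)[q])
  }
  hpairs <- list(c(2, 9, 10, 1, 3), c(3, 11, 12, 2, 4), c(4, 13, 14, 3, 5))
  for (hp in hpairs) {
    xyz[hp[2], ] <- place_atom(xyz[hp[4], ], xyz[hp[5], ], xyz[hp[1], ],
                               1.09, 109, 120)
    xyz[hp[3], ] <- place_atom(xyz[hp[4], ], xyz[hp[5], ], xyz[hp[1], ],
                               1.09, 109, -120)
  }
  for (q in 1:3) {
    xyz[14 + q, ] <- place_atom(xyz[3, ], xyz[4, ], xyz[5, ], 1.09, 110,
                                c(180, 60, -60)[q])
  }
  system <- build_system(list(atoms = atoms, bonds = bonds,
                              torsions = torsions))
  system <- rebuild_with_angle_params(system, atoms, bonds, torsions, el)
  info <- list(
    kind = "chain",
    rotor = c(1, 2, 3, 4),
    moving = c(4, 5, 11:17),
    methyls = list(c(1, 6, 7, 8), c(5, 15, 16, 17)),
    methine = list(c(2, 9), c(3, 11)),
    protons = 6:17)
  list(system = system, conformation = conformation(xyz), info = info,
       datasets = NULL)
}

#' Sample a reference ensemble with known rotamer populations
#'
#' Frames are generated by drawing the soft rotor torsion from a von Mises
#' mixture centred at 180/-60/+60 degrees with the requested weights,
#' rotating the moving fragment accordingly, and adding small Gaussian
#' Cartesian jitter. The fragment carrying the rotor's first atom keeps a
#' fixed orientation, which defines the molecular frame in which the
#' imposed alignment tensor of [synthesize_constraints()] lives.
#'
#' @param toy result of [make_toy_molecule()].
#' @param populations named fractions for `trans`, `gauche-`, `gauche+`
#'   (must sum to 1).
#' @param n_frames ensemble size.
#' @param seed RNG seed.
#' @param kappa von Mises concentration (about (1/kappa)^0.5 rad spread).
#' @param jitter Cartesian jitter sd, A.
#' @return object of class `reference_ensemble`.
#' @export
generate_reference_ensemble <- function(toy, populations, n_frames = 5000,
                                        seed = 1, kappa = 50, jitter = 0.02) {
  if (abs(sum(populations) - 1) > 1e-8) stop("populations must sum to 1")
  states <- c("trans", "gauche-", "gauche+")
  pops <- populations[states]
  pops[is.na(pops)] <- 0
  centers <- c(trans = 180, `gauche-` = -60, `gauche+` = 60)
  set.seed(seed)
  draw <- sample(states, n_frames, replace = TRUE, prob = pops)
  base <- toy$conformation$xyz
  coords <- vector("list", n_frames)
  omegas <- numeric(n_frames)
  for (f in seq_len(n_frames)) {
    om <- rvonmises(1, centers[[draw[f]]], kappa)
    x <- set_rotor_angle(base, toy$info, om)
    x <- x + matrix(stats::rnorm(length(x), 0, jitter), nrow(x), 3)
    coords[[f]] <- x
    omegas[f] <- dihedral_angle(x, toy$info$rotor)
  }
  structure(list(coords = coords, states = rotamer_state(omegas),
                 omegas = omegas, base_xyz = base, system = toy$system,
                 info = toy$info, datasets = toy$datasets,
                 populations = pops, seed = seed),
            class = "reference_ensemble")
}

# rotate the moving fragment about the rotor bond so the rotor dihedral
# becomes `target` (degrees)
set_rotor_angle <- function(xyz, info, target) {
  cur <- dihedral_angle(xyz, info$rotor)
  ax <- xyz[info$rotor[3], ] - xyz[info$rotor[2], ]
  out <- xyz
  out[info$moving, ] <- rotate_about_axis(xyz[info$moving, , drop = FALSE],
                                          xyz[info$rotor[3], ], ax,
                                          target - cur)
  out
}

#' @export
print.reference_ensemble <- function(x, ...) {
  cat("<reference_ensemble>", length(x$coords), "frames; fractions:",
      paste(sprintf("%s %.3f", names(table(x$states)),
                    as.numeric(table(x$states)) / length(x$states)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Synthesize noisy pseudo-experimental constraint tables
#'
#' Forward model inverse to the fitting stack: RDCs are the ensemble
#' averages of `D_stat * (direction cosines . Saupe)` under one common
#' imposed alignment tensor (methyl RDCs averaged over the three C-H
#' bonds), NOE targets are ensemble `<r^-6>^(-1/6)` distances, and 3J
#' values ensemble-averaged Karplus couplings; Gaussian noise is added and
#' the error column is `max(noise sigma, floor)`.
#'
#' @param ensemble a `reference_ensemble` (from a toy with `datasets`).
#' @param saupe imposed Saupe tensor, 5 components
#'   (S_zz, S_xx - S_yy, S_xy, S_xz, S_yz), dimensionless.
#' @param noise named sigmas `c(rdc = , noe = , j = )` (Hz, A, Hz).
#' @param error_floor per-type error floors for the tables' error column.
#' @param seed RNG seed for the noise.
#' @return list of tibbles `rdc`, `noe`, `j` (the dialects consumed by
#'   [run_mdoc()] and the readers) plus a `manifest` tibble.
#' @export
synthesize_constraints <- function(ensemble,
                                   saupe = c(4e-4, 2.5e-4, 1e-4, 0.5e-4, 1.5e-4),
                                   noise = c(rdc = 0.3, noe = 0.1, j = 0.3),
                                   error_floor = c(rdc = 1.0, noe = 0.5, j = 1.0),
                                   seed = 1) {
  if (!length(ensemble$coords)) stop("empty ensemble")
  defs <- ensemble$datasets
  if (is.null(defs)) stop("toy molecule carries no constraint definitions")
  set.seed(seed)
  base <- ensemble$base_xyz
  frames <- ensemble$coords

  rdc <- defs$rdc
  d_exp <- numeric(nrow(rdc)); d_stat <- numeric(nrow(rdc))
  for (r in seq_len(nrow(rdc))) {
    pairs <- if (rdc$class[r] == "methyl") {
      cbind(rdc$i[r], c(rdc$j[r], rdc$h2[r], rdc$h3[r]))
    } else cbind(rdc$i[r], rdc$j[r])
    ds <- if (rdc$class[r] == "long-range") {
      rr <- sqrt(sum((base[pairs[1, 1], ] - base[pairs[1, 2], ])^2))
      .hh_dipolar_prefactor * 1000 / rr^3
    } else d_stat_default("ch_sp3")
    d_stat[r] <- ds
    acc <- 0
    for (x in frames) {
      for (q in seq_len(nrow(pairs))) {
        d <- x[pairs[q, 1], ] - x[pairs[q, 2], ]
        u <- d / sqrt(sum(d^2))
        cf <- c((3 * u[3]^2 - 1) / 2, (u[1]^2 - u[2]^2) / 2,
                2 * u[1] * u[2], 2 * u[1] * u[3], 2 * u[2] * u[3])
        acc <- acc + sum(cf * saupe) / nrow(pairs)
      }
    }
    d_exp[r] <- ds * acc / length(frames)
  }
  rdc_tbl <- rdc_table(rdc$id, rdc$class, rdc$i, rdc$j, rdc$h2, rdc$h3,
                       d_exp = d_exp + stats::rnorm(nrow(rdc), 0, noise[["rdc"]]),
                       error = max(noise[["rdc"]], error_floor[["rdc"]]),
                       d_stat = d_stat)

  noe <- defs$noe
  target <- numeric(nrow(noe))
  for (p in seq_len(nrow(noe))) {
    partners <- c(noe$j[p], noe$h2[p], noe$h3[p])
    partners <- partners[!is.na(partners)]
    r6 <- 0
    for (x in frames) {
      for (q in partners) {
        r6 <- r6 + sum((x[noe$i[p], ] - x[q, ])^2)^-3 / length(partners)
      }
    }
    target[p] <- (r6 / length(frames))^(-1 / 6)
  }
  noe_tbl <- noe_table(noe$id, noe$i, noe$j, noe$h2, noe$h3,
                       target = target + stats::rnorm(nrow(noe), 0, noise[["noe"]]),
                       error = max(noise[["noe"]], error_floor[["noe"]]))

  jt <- defs$j
  j_exp <- numeric(nrow(jt))
  for (t_ in seq_len(nrow(jt))) {
    chi <- parse_numlist(jt$chi[t_]); xi <- parse_numlist(jt$xi[t_])
    ps <- haasnoot_params(jt$param_set[t_])
    phis <- vapply(frames, dihedral_angle, numeric(1),
                   idx = c(jt$i[t_], jt$j[t_], jt$k[t_], jt$l[t_]))
    j_exp[t_] <- mean(karplus_haasnoot(phis, chi, xi, ps))
  }
  j_tbl <- j_table(jt$id, jt$i, jt$j, jt$k, jt$l,
                   j_exp = j_exp + stats::rnorm(nrow(jt), 0, noise[["j"]]),
                   error = max(noise[["j"]], error_floor[["j"]]),
                   chi = jt$chi, xi = jt$xi, param_set = jt$param_set)

  manifest <- tibble::tibble(
    seed = seed, ensemble_seed = ensemble$seed,
    n_frames = length(frames),
    saupe = paste(signif(saupe, 6), collapse = ","),
    noise = paste(sprintf("%s=%g", names(noise), noise), collapse = ","),
    populations = paste(sprintf("%s=%g", names(ensemble$populations),
                                ensemble$populations), collapse = ","))
  list(rdc = rdc_tbl, noe = noe_tbl, j = j_tbl, manifest = manifest)
}
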