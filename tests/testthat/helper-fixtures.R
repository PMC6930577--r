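# Shared fixtures, memoised so the toy molecule and reference ensemble are
# built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

toy_fixture <- function() fixture("toy", function() make_toy_molecule("single-rotor"))

ensemble_fixture <- function() {
  fixture("ens", function() {
    generate_reference_ensemble(
      toy_fixture(), c(trans = 0.7, `gauche-` = 0.3, `gauche+` = 0),
      n_frames = 4000, seed = 11)
  })
}

tables_fixture <- function() {
  fixture("tabs", function() synthesize_constraints(ensemble_fixture(), seed = 11))
}

# an ethane-like two-heavy-atom topology: 8 atoms, 7 bonds
ethane_topology <- function() {
  list(
    atoms = tibble::tibble(
      name = c("C1", "C2", paste0("H", 1:6)),
      element = c("C", "C", rep("H", 6)),
      mass = c(12.011, 12.011, rep(1.008, 6)),
      charge = c(-0.09, -0.09, rep(0.03, 6)),
      sigma = c(3.4, 3.4, rep(2.5, 6)),
      epsilon = c(0.36, 0.36, rep(0.08, 6))),
    bonds = tibble::tibble(
      i = c(1, 1, 1, 1, 2, 2, 2),
      j = c(2, 3, 4, 5, 6, 7, 8),
      r0 = c(1.54, rep(1.09, 6)),
      k = c(2600, rep(2900, 6))))
}

# central finite-difference gradient of a scalar function of coordinates
fd_gradient <- function(f, x, h = 1e-6, atoms = seq_len(nrow(x))) {
  g <- matrix(0, nrow(x), 3)
  for (i in atoms) {
    for (q in 1:3) {
      xa <- x; xb <- x
      xa[i, q] <- xa[i, q] + h
      xb[i, q] <- xb[i, q] - h
      g[i, q] <- (f(xa) - f(xb)) / (2 * h)
    }
  }
  g
}

net_torque <- function(x, forces) {
  colSums(t(vapply(seq_len(nrow(x)),
                   function(i) c(x[i, 2] * forces[i, 3] - x[i, 3] * forces[i, 2],
                                 x[i, 3] * forces[i, 1] - x[i, 1] * forces[i, 3],
                                 x[i, 1] * forces[i, 2] - x[i, 2] * forces[i, 1]),
                   numeric(3))))
}

# internal geometry utilities used across tests
place_atom <- mdoc:::place_atom
random_rotation <- mdoc:::random_rotation
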