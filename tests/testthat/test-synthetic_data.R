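# Toy molecules, reference ensembles and the forward constraint model.

test_that("single-rotor toy molecule is valid, clash-free and has one soft
           torsion", {
  toy <- toy_fixture()
  sys <- toy$system
  expect_s3_class(sys, "molecular_system")
  n <- nrow(sys$atoms)
  expect_gte(n, 15); expect_lte(n, 40)
  expect_gte(length(toy$info$methyls), 2)
  expect_gte(length(toy$info$protons), 8)
  soft <- sys$torsions$v < 15
  expect_equal(sum(soft), 1)
  expect_equal(unlist(sys$torsions[soft, c("i", "j", "k", "l")],
                      use.names = FALSE), toy$info$rotor)
  x <- toy$conformation$xyz
  prs <- sys$pairs
  dmin <- min(sqrt(rowSums((x[prs$i, ] - x[prs$j, ])^2)))
  expect_gt(dmin, 1.8)
  chain <- make_toy_molecule("chain")
  expect_s3_class(chain$system, "molecular_system")
  expect_gte(nrow(chain$system$atoms), 15)
  expect_error(make_toy_molecule("ring"))
})

test_that("reference ensembles hit the requested rotamer fractions", {
  toy <- toy_fixture()
  ens1 <- generate_reference_ensemble(toy, c(trans = 1, `gauche-` = 0,
                                             `gauche+` = 0),
                                      n_frames = 300, seed = 1)
  expect_true(all(ens1$states == "trans"))
  ens <- generate_reference_ensemble(toy, c(trans = 0.7, `gauche-` = 0.3,
                                            `gauche+` = 0),
                                     n_frames = 10000, seed = 2)
  fr <- rotamer_populations(ens$omegas)$fractions
  expect_lt(abs(fr[["trans"]] - 0.7), 0.02)
  expect_lt(abs(fr[["gauche-"]] - 0.3), 0.02)
  ens_b <- generate_reference_ensemble(toy, c(trans = 0.7, `gauche-` = 0.3,
                                              `gauche+` = 0),
                                       n_frames = 10000, seed = 3)
  fr_b <- rotamer_populations(ens_b$omegas)$fractions
  expect_false(identical(ens$coords[[1]], ens_b$coords[[1]]))
  expect_true(all(abs(fr - fr_b) < 0.03))
  expect_error(generate_reference_ensemble(toy, c(trans = 0.7,
                                                  `gauche-` = 0.7,
                                                  `gauche+` = 0),
                                           n_frames = 10),
               "sum to 1")
})

test_that("an isotropically reoriented ensemble averages all RDCs to zero", {
  toy <- toy_fixture()
  ens <- generate_reference_ensemble(toy, c(trans = 0.7, `gauche-` = 0.3,
                                            `gauche+` = 0),
                                     n_frames = 600, seed = 4, jitter = 0)
  set.seed(5)
  ens$coords <- lapply(ens$coords, function(x) x %*% t(random_rotation()))
  tabs <- synthesize_constraints(ens, noise = c(rdc = 0, noe = 0, j = 0),
                                 seed = 5)
  # isotropic average of P2 is zero; residual is sampling noise ~ n^-1/2
  scale_hz <- abs(tabs$rdc$d_stat) * 6e-4   # forward-model magnitude scale
  expect_true(all(abs(tabs$rdc$d_exp) < 5 * scale_hz / sqrt(600) + 1e-3))
})

test_that("a single rigid frame round-trips through fit_saupe exactly", {
  toy <- toy_fixture()
  ens <- generate_reference_ensemble(toy, c(trans = 1, `gauche-` = 0,
                                            `gauche+` = 0),
                                     n_frames = 1, seed = 6, kappa = 400,
                                     jitter = 0)
  saupe <- c(4e-4, 2.5e-4, 1e-4, 0.5e-4, 1.5e-4)
  tabs <- synthesize_constraints(ens, saupe = saupe,
                                 noise = c(rdc = 0, noe = 0, j = 0), seed = 7)
  vec_rows <- tabs$rdc[tabs$rdc$class != "methyl", ]
  fit <- fit_saupe(ens$coords[[1]], vec_rows)
  expect_equal(fit$saupe, saupe, tolerance = 1e-6)
  expect_lt(fit$q, 1e-6)
  # NOE targets equal the instantaneous distances of that frame
  x <- ens$coords[[1]]
  single <- is.na(tabs$noe$h2)
  d <- sqrt(rowSums((x[tabs$noe$i[single], ] - x[tabs$noe$j[single], ])^2))
  expect_equal(tabs$noe$target[single], d, tolerance = 1e-9)
  # 3J values equal the Karplus couplings of that frame
  jt <- tabs$j
  for (q in seq_len(nrow(jt))) {
    phi <- dihedral_angle(x, c(jt$i[q], jt$j[q], jt$k[q], jt$l[q]))
    ref <- karplus_haasnoot(phi, mdoc:::parse_numlist(jt$chi[q]),
                            mdoc:::parse_numlist(jt$xi[q]),
                            haasnoot_params(jt$param_set[q]))
    expect_equal(jt$j_exp[q], ref, tolerance = 1e-9)
  }
})

test_that("synthetic tables carry error floors and the dataset shape", {
  tabs <- tables_fixture()
  expect_true(all(tabs$rdc$error >= 1.0))
  expect_true(all(tabs$noe$error >= 0.5))
  expect_true(all(tabs$j$error >= 1.0))
  cc <- constraint_counts(tabs)
  expect_equal(unname(cc), c(6L, 8L, 7L, 5L))
  expect_true(all(abs(tabs$rdc$d_exp) <= 0.004 * abs(tabs$rdc$d_stat)))
  expect_equal(nrow(tabs$manifest), 1)
})
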