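# Dipolar tensors, frame transformations and tensorial pseudo-forces.

test_that("PAS tensor scales the static splitting by the order parameter", {
  t1 <- pas_tensor(47960, 0.004)
  expect_equal(t1[3, 3], 191.84)
  expect_equal(t1[1, 1], -191.84 / 2)
  expect_equal(sum(diag(t1)), 0)
  t2 <- pas_tensor(2, 1)
  expect_equal(unclass(t2), diag(c(-1, -1, 2)), ignore_attr = TRUE)
  expect_error(pas_tensor(0, 0.004))
  expect_error(pas_tensor(47960, 1.5))
})

test_that("lab tensor follows the P2 law for tilted bonds", {
  pas <- pas_tensor(1000, 0.1)  # D = 100 Hz
  x <- rbind(c(0, 0, 0), c(0, 0, 1.5))
  along_z <- lab_tensor(x, c(2, 1), pas)
  expect_equal(unclass(along_z), unclass(pas), tolerance = 1e-12,
               ignore_attr = TRUE)
  xx <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  along_x <- lab_tensor(xx, c(2, 1), pas)
  expect_equal(along_x[3, 3], -50, tolerance = 1e-12)
  # magic angle and random tilts: zz = D * P2(cos theta)
  th_magic <- acos(1 / sqrt(3)) * 180 / pi
  for (th in c(th_magic, 10, 30, 60, 85)) {
    v <- c(sin(th * pi / 180), 0, cos(th * pi / 180)) * 2
    xt <- rbind(c(0, 0, 0), v)
    lt <- lab_tensor(xt, c(2, 1), pas)
    p2 <- (3 * cos(th * pi / 180)^2 - 1) / 2
    expect_lt(abs(lt[3, 3] - 100 * p2), 1e-8)
  }
  am <- acos(1 / sqrt(3))
  expect_lt(abs(lab_tensor(rbind(c(0, 0, 0), 2 * c(sin(am), 0, cos(am))),
                           c(2, 1), pas)[3, 3]), 1e-8)
})

test_that("lab tensor keeps its eigenvalues under random rotations and is
           even in the internuclear vector", {
  pas <- pas_tensor(47960, 0.004)
  set.seed(11)
  x <- rbind(c(0.3, -0.2, 0.5), c(1.1, 0.7, -0.4))
  ref <- sort(eigen(unclass(lab_tensor(x, c(1, 2), pas)))$values)
  for (rep in 1:100) {
    R <- random_rotation()
    lt <- lab_tensor(x %*% t(R), c(1, 2), pas)
    expect_equal(sort(eigen(unclass(lt))$values), ref, tolerance = 1e-9)
  }
  swapped <- lab_tensor(x, c(2, 1), pas)
  expect_equal(unclass(swapped), unclass(lab_tensor(x, c(1, 2), pas)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(lab_tensor(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 2), pas),
               "zero-length")
})

test_that("experimental tensor is diagonal, traceless and axial", {
  expect_equal(unclass(exp_tensor(0)), matrix(0, 3, 3), ignore_attr = TRUE)
  e <- exp_tensor(4)
  expect_equal(diag(e), c(-2, -2, 4), ignore_attr = TRUE)
  expect_equal(sum(diag(e)), 0)
  expect_true(all(e[upper.tri(e)] == 0))
})

test_that("tanh scale is odd, saturating and overflow-safe", {
  expect_equal(tanh_scale(0, 0.5), 0)
  expect_equal(tanh_scale(1, 1), tanh(1))
  expect_equal(tanh_scale(-10 * 0.5, 0.5), -1, tolerance = 1e-8)
  expect_equal(tanh_scale(1e6, 0.5), 1)
  expect_equal(tanh_scale(-3, 0.5), -tanh_scale(3, 0.5))
  expect_error(tanh_scale(1, 0))
})

test_that("RDC pseudo-forces are equal/opposite, orientational and match
           finite differences of the tanh-integrated pseudo-energy", {
  toy <- toy_fixture()
  pas <- pas_tensor(47960, 0.004)
  dmax <- 0.004 * 47960
  set.seed(21)
  for (rep in 1:10) {
    x <- toy$conformation$xyz + matrix(rnorm(60, 0, 0.05), 20, 3)
    pair <- c(2, 7)
    mem <- matrix(rnorm(9, 0, 3), 3, 3)
    mem <- (mem + t(mem)) / 2
    F <- rdc_pseudo_force(x, pair, mem, d_exp = 4, d_max = dmax,
                          width = 0.5, k = 0.02)
    u <- x[pair[1], ] - x[pair[2], ]
    u <- u / sqrt(sum(u^2))
    expect_lt(max(abs(F[pair[1], ] + F[pair[2], ])), 1e-12)
    expect_lt(abs(sum(F[pair[1], ] * u)) / max(abs(F)), 1e-10)
  }
  # finite-difference oracle: frozen memory tracking the instantaneous
  # tensor, energy = sum over components of width * log cosh(delta/width)
  x <- toy$conformation$xyz
  pair <- c(3, 8)
  d_exp <- 6; width <- 0.5; k <- 0.02
  e_pseudo <- function(xx) {
    lt <- unclass(lab_tensor(xx, pair, pas))
    k * sum(width * log(cosh((lt - unclass(exp_tensor(d_exp))) / width)))
  }
  Fa <- rdc_pseudo_force(x, pair, unclass(lab_tensor(x, pair, pas)),
                         d_exp, dmax, width, k)
  num <- -fd_gradient(e_pseudo, x, h = 1e-7, atoms = pair)
  expect_lt(max(abs(num - Fa)) / max(abs(Fa)), 1e-6)
})

test_that("methyl observable averages the three bond tensors", {
  toy <- toy_fixture()
  x <- toy$conformation$xyz
  pas <- pas_tensor(47960, 0.004)
  D <- 191.84
  pairs <- rbind(c(1, 9), c(1, 10), c(1, 11))
  mt <- methyl_rdc_observable(x, pairs, pas)
  expect_lt(abs(sum(diag(mt))), 1e-9)
  direct <- (unclass(lab_tensor(x, pairs[1, ], pas)) +
             unclass(lab_tensor(x, pairs[2, ], pas)) +
             unclass(lab_tensor(x, pairs[3, ], pas))) / 3
  expect_equal(unclass(mt), direct, tolerance = 1e-12, ignore_attr = TRUE)
  # ideal tetrahedral methyl with its symmetry axis along z: the averaged
  # tensor is the single-axis tensor scaled by P2(cos(70.53 deg)) = -1/3
  c0 <- c(0, 0, 0)
  hb <- 70.5287794 * pi / 180   # angle of each C-H bond to the methyl axis
  hs <- t(vapply(0:2, function(kk) {
    phi <- 2 * pi * kk / 3
    1.09 * c(sin(hb) * cos(phi), sin(hb) * sin(phi), cos(hb))
  }, numeric(3)))
  xm <- rbind(c0, hs)
  mt2 <- methyl_rdc_observable(xm, rbind(c(1, 2), c(1, 3), c(1, 4)), pas)
  expect_equal(mt2[3, 3], D * (3 * cos(hb)^2 - 1) / 2, tolerance = 1e-6)
  expect_equal(mt2[3, 3], -D / 3, tolerance = 1e-3)
  expect_lt(max(abs(mt2[1, 2]), abs(mt2[1, 3]), abs(mt2[2, 3])), 1e-9)
  # parallel bonds degenerate to the single-bond tensor
  xp <- rbind(c0, c(0, 0, 1.09), c(0.5, 0, 1.09) - c(0.5, 0, 0),
              c(0, 0.5, 1.09) - c(0, 0.5, 0))
  mtp <- methyl_rdc_observable(xp, rbind(c(1, 2), c(1, 3), c(1, 4)), pas)
  expect_equal(unclass(mtp), unclass(lab_tensor(xp, c(1, 2), pas)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(methyl_rdc_observable(x, rbind(c(1, 9), c(5, 12), c(1, 11)),
                                     pas), "share the carbon")
})

test_that("isotropic orientation sampling drives all nine tensor components
           to zero", {
  pas <- pas_tensor(47960, 0.004)
  set.seed(31)
  n <- 20000
  comps <- matrix(0, n, 9)
  x0 <- rbind(c(0, 0, 0), c(0, 0, 1.09))
  for (s in seq_len(n)) {
    R <- random_rotation()
    comps[s, ] <- as.vector(t(unclass(lab_tensor(x0 %*% t(R), c(1, 2), pas))))
  }
  mem <- memory_state(tau = 1e9, dim = 9)
  for (s in seq_len(n)) mem <- update_memory(mem, comps[s, ], 1)
  m <- memory_mean(mem)
  se <- apply(comps, 2, stats::sd) / sqrt(n)
  expect_true(all(abs(m) < 3 * se))
})
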