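# Torsion series, rotamer binning and complex dihedral PCA.

test_that("dihedral sign convention: cis 0, trans 180, mirror negates", {
  x <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0))   # cis
  expect_equal(dihedral_angle(x, 1:4), 0, tolerance = 1e-10)
  xt <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, -1, 0)) # trans
  expect_equal(abs(dihedral_angle(xt, 1:4)), 180, tolerance = 1e-10)
  xg <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0),
              place_atom(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), 1, 90, 55))
  a <- dihedral_angle(xg, 1:4)
  expect_equal(a, 55, tolerance = 1e-6)
  xm <- xg; xm[, 3] <- -xm[, 3]   # mirror image
  expect_equal(dihedral_angle(xm, 1:4), -a, tolerance = 1e-6)
  xc <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_error(dihedral_angle(xc, 1:4), "collinear")
})

test_that("rotamer binning matches the three-state boundaries", {
  r <- rotamer_populations(rep(175, 40))
  expect_equal(unname(r$fractions), c(1, 0, 0))
  r2 <- rotamer_populations(c(60, -60, 180))
  expect_equal(unname(r2$fractions), c(1, 1, 1) / 3)
  set.seed(71)
  r3 <- rotamer_populations(runif(30000, -180, 180))
  expect_true(all(abs(r3$fractions - 1 / 3) < 0.02))
  expect_equal(sum(r3$fractions), 1)
  # boundary placement
  expect_equal(unname(rotamer_populations(c(120, -120))$fractions[1]), 1)
  expect_equal(unname(rotamer_populations(c(119, 1))$fractions[3]), 1)
  expect_equal(unname(rotamer_populations(c(-119, 0))$fractions[2]), 1)
})

test_that("torsion series over frames equals per-frame binning", {
  toy <- toy_fixture()
  ens <- ensemble_fixture()
  ang <- torsion_series(ens, toy$info$rotor)
  expect_length(ang, length(ens$coords))
  direct <- vapply(ens$coords, dihedral_angle, numeric(1), idx = toy$info$rotor)
  expect_equal(ang, direct)
  expect_equal(rotamer_populations(ang)$fractions,
               rotamer_populations(direct)$fractions)
})

test_that("dPCA isolates a single active dihedral", {
  set.seed(72)
  n <- 600
  active <- ifelse(runif(n) < 0.5, -60, 180) + rnorm(n, 0, 8)
  frozen1 <- rnorm(n, 40, 1)
  frozen2 <- rnorm(n, -100, 1)
  res <- dpca(cbind(a = active, f1 = frozen1, f2 = frozen2))
  expect_gt(res$contributions[1, 1], 0.99)
  expect_equal(sum(res$values), res$total_variance, tolerance = 1e-8)
  expect_true(all(abs(colSums(res$contributions^2) - 1) < 1e-9))
})

test_that("dPCA is permutation-equivariant and ignores frozen dihedrals", {
  set.seed(73)
  n <- 400
  a <- ifelse(runif(n) < 0.6, 175, -65) + rnorm(n, 0, 10)
  b <- a + rnorm(n, 0, 15)   # correlated partner
  c_ <- rnorm(n, 60, 6)
  m <- cbind(a, b, c_)
  r1 <- dpca(m)
  r2 <- dpca(m[, c(3, 1, 2)])
  expect_equal(sort(r1$values), sort(r2$values), tolerance = 1e-10)
  expect_equal(sort(r1$contributions[, 1]), sort(r2$contributions[, 1]),
               tolerance = 1e-8)
  r3 <- dpca(cbind(m, d = rep(100, n)))
  expect_equal(sort(r1$values), sort(r3$values[r3$values > 1e-12]),
               tolerance = 1e-10)
  expect_lt(abs(sum(r3$values) - sum(r1$values)), 1e-10)
})

test_that("two-state exchange on correlated dihedrals separates in theta_1", {
  set.seed(74)
  n <- 800
  state <- runif(n) < 0.5
  d1 <- ifelse(state, 170, -70) + rnorm(n, 0, 9)
  d2 <- ifelse(state, -60, 60) + rnorm(n, 0, 9)
  res <- dpca(cbind(d1, d2))
  th1 <- res$theta[, 1]
  mu_a <- atan2(mean(sin(th1[state] * pi / 180)),
                mean(cos(th1[state] * pi / 180))) * 180 / pi
  mu_b <- atan2(mean(sin(th1[!state] * pi / 180)),
                mean(cos(th1[!state] * pi / 180))) * 180 / pi
  sep <- abs(((mu_a - mu_b + 180) %% 360) - 180)
  spread_a <- stats::sd(((th1[state] - mu_a + 180) %% 360) - 180)
  spread_b <- stats::sd(((th1[!state] - mu_b + 180) %% 360) - 180)
  expect_gt(sep, 3 * (spread_a + spread_b) / 2)  # clearly bimodal
  expect_error(dpca(matrix(50, 10, 2)), "zero covariance")
})
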