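# Saupe alignment-tensor SVD fitting: coefficients, round trips and the
# population-weighted multi-conformer search.

random_vectors_structure <- function(n, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(6 * n), 2 * n, 3)
  rdc <- tibble::tibble(i = seq(1, 2 * n, by = 2), j = seq(2, 2 * n, by = 2),
                        d_stat = 47960)
  list(x = x, rdc = rdc)
}

forward_rdc <- function(x, rdc, saupe) {
  as.vector(direction_cosine_matrix(x, rdc) %*% saupe)
}

test_that("coefficient rows follow the chosen Saupe parametrisation", {
  x <- rbind(c(0, 0, 0), c(0, 0, 1.09))
  rdc <- tibble::tibble(i = 2, j = 1, d_stat = 1)
  A <- direction_cosine_matrix(x, rdc)
  expect_equal(as.vector(A), c(1, 0, 0, 0, 0), tolerance = 1e-12)
  s <- random_vectors_structure(6, seed = 2)
  A2 <- direction_cosine_matrix(s$x, s$rdc)
  expect_lte(qr(A2)$rank, 5)
  # duplicated vector duplicates the row without raising the rank
  s$rdc2 <- dplyr::bind_rows(s$rdc, s$rdc[1, ])
  A3 <- direction_cosine_matrix(s$x, s$rdc2)
  expect_equal(A3[nrow(A3), ], A3[1, ])
  expect_equal(qr(A3)$rank, qr(A2)$rank)
})

test_that("noiseless synthetic RDCs return the generating tensor exactly", {
  s <- random_vectors_structure(9, seed = 3)
  saupe <- c(4e-4, 2.5e-4, 1e-4, 0.5e-4, 1.5e-4)
  d <- forward_rdc(s$x, s$rdc, saupe)
  rdc <- dplyr::mutate(s$rdc, d_exp = d, error = 1)
  fit <- fit_saupe(s$x, rdc)
  expect_equal(fit$saupe, saupe, tolerance = 1e-8)
  expect_lt(fit$q, 1e-10)
  expect_gt(fit$quality, 1e6)   # chi2 at numerical-noise level
  expect_equal(sum(diag(fit$saupe_matrix)), 0, tolerance = 1e-12)
  expect_equal(fit$saupe_matrix, t(fit$saupe_matrix))
  # self-fit on back-calculated values
  rdc2 <- dplyr::mutate(rdc, d_exp = fit$back_calculated)
  fit2 <- fit_saupe(s$x, rdc2)
  expect_lt(fit2$q, 1e-10)
})

test_that("underdetermined and degenerate inputs are flagged", {
  s <- random_vectors_structure(4, seed = 4)
  rdc <- dplyr::mutate(s$rdc, d_exp = 1, error = 1)
  expect_error(fit_saupe(s$x, rdc), "underdetermined")
  # all vectors in the xy-plane: condition number far above a 3D set
  n <- 8
  set.seed(5)
  ang <- runif(n, 0, 2 * pi)
  xpl <- matrix(0, 2 * n, 3)
  for (q in seq_len(n)) {
    xpl[2 * q - 1, ] <- c(0, 0, 0)
    xpl[2 * q, ] <- c(cos(ang[q]), sin(ang[q]), 0)
  }
  rdcp <- tibble::tibble(i = seq(1, 2 * n, 2), j = seq(2, 2 * n, 2),
                         d_stat = 47960,
                         d_exp = rnorm(n), error = 1)
  fitp <- suppressWarnings(fit_saupe(xpl, rdcp))
  s3 <- random_vectors_structure(n, seed = 6)
  rdc3 <- dplyr::mutate(s3$rdc, d_exp = rnorm(n), error = 1)
  fit3 <- fit_saupe(s3$x, rdc3)
  expect_gt(fitp$condition / fit3$condition, 100)
})

test_that("Q is invariant when the structure is rotated and the tensor refit", {
  s <- random_vectors_structure(8, seed = 7)
  saupe <- c(3e-4, -1e-4, 2e-4, 1e-4, -0.5e-4)
  set.seed(8)
  d <- forward_rdc(s$x, s$rdc, saupe) + rnorm(8, 0, 0.4)
  rdc <- dplyr::mutate(s$rdc, d_exp = d, error = 1)
  q0 <- fit_saupe(s$x, rdc)$q
  for (rep in 1:5) {
    R <- random_rotation()
    expect_equal(fit_saupe(s$x %*% t(R), rdc)$q, q0, tolerance = 1e-8)
  }
})

test_that("population-weighted fit recovers a 60/40 two-conformer mixture", {
  toy <- toy_fixture()
  xa <- toy$conformation$xyz
  xb <- mdoc:::set_rotor_angle(xa, toy$info, -60)
  rdc_def <- toy$datasets$rdc[toy$datasets$rdc$class != "methyl", ]
  rdc_def <- tibble::tibble(i = rdc_def$i, j = rdc_def$j, d_stat = 47960)
  saupe <- c(4e-4, 2.5e-4, 1e-4, 0.5e-4, 1.5e-4)
  d <- 0.6 * forward_rdc(xa, rdc_def, saupe) +
       0.4 * forward_rdc(xb, rdc_def, saupe)
  rdc <- dplyr::mutate(rdc_def, d_exp = d, error = 1)
  fit <- multi_conformer_fit(list(xa, xb), rdc, step = 0.05)
  expect_equal(fit$populations, c(0.6, 0.4), tolerance = 0.051)
  expect_lt(fit$chisq, 1e-10)
  # grid containing (1, 0) with single-conformer truth reduces to fit_saupe
  d1 <- forward_rdc(xa, rdc_def, saupe)
  rdc1 <- dplyr::mutate(rdc_def, d_exp = d1, error = 1)
  fit1 <- multi_conformer_fit(list(xa, xb), rdc1, step = 0.05)
  expect_equal(fit1$populations, c(1, 0), tolerance = 1e-12)
  ref <- fit_saupe(xa, rdc1)
  expect_equal(fit1$saupe, ref$saupe, tolerance = 1e-8)
  # identical conformers: chi-squared is flat across the grid
  fit_same <- multi_conformer_fit(list(xa, xa), rdc1, step = 0.25)
  expect_lt(diff(range(fit_same$population_grid$chisq)), 1e-8)
  # multi-conformer chi2 never exceeds the best single conformer
  set.seed(9)
  dmix <- d + rnorm(length(d), 0, 0.3)
  rdcm <- dplyr::mutate(rdc_def, d_exp = dmix, error = 1)
  fitm <- multi_conformer_fit(list(xa, xb), rdcm, step = 0.05)
  best_single <- min(fit_saupe(xa, rdcm)$chisq, fit_saupe(xb, rdcm)$chisq)
  expect_lte(fitm$chisq, best_single + 1e-10)
  expect_error(multi_conformer_fit(list(xa, xb[-1, ]), rdcm),
               "inconsistent atom sets")
})
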