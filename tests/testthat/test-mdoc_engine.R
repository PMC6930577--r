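# Exponential-memory averaging, the pseudo-force ramp, the integrator and
# the restrained run orchestration.

test_that("exponential memory reproduces a constant signal exactly", {
  mem <- memory_state(tau = 200)
  for (s in 1:50) mem <- update_memory(mem, 3.7, 0.5)
  expect_equal(memory_mean(mem), 3.7)
})

test_that("less than 1 percent of a switched-off signal survives 5 tau", {
  tau <- 20
  mem <- memory_state(tau)
  for (s in 1:200) mem <- update_memory(mem, 1, 0.1)   # 20 ps of ones = tau
  for (s in 1:1000) mem <- update_memory(mem, 0, 0.1)  # 100 ps = 5 tau of zeros
  expect_lt(memory_mean(mem), 0.01)
})

test_that("memory recursion equals direct evaluation of the weighted integral", {
  set.seed(5)
  tau <- 0.5; dt <- 0.01
  vals <- rnorm(500)
  mem <- memory_state(tau)
  for (v in vals) mem <- update_memory(mem, v, dt)
  w <- exp(-(length(vals):1 - 1) * dt / tau)
  direct <- sum(w * vals * dt) / sum(w * dt)
  expect_lt(abs(memory_mean(mem) - direct) / abs(direct), 1e-8)
})

test_that("tensor memory is componentwise and stays within the value envelope", {
  set.seed(6)
  mem <- memory_state(tau = 1, dim = 9)
  vals <- matrix(rnorm(9 * 100), 100, 9)
  for (r in seq_len(nrow(vals))) mem <- update_memory(mem, vals[r, ], 0.05)
  m <- memory_mean(mem)
  expect_length(m, 9)
  expect_true(all(m >= apply(vals, 2, min) & m <= apply(vals, 2, max)))
})

test_that("pseudo-force ramp follows 1 - exp(-t/rho)", {
  expect_equal(ramp_factor(0, 100), 0)
  expect_equal(ramp_factor(100, 100), 1 - exp(-1))
  expect_gt(ramp_factor(1000, 100), 0.9999)
  expect_error(ramp_factor(1, -1))
})

test_that("harmonic bond oscillation matches the analytic period within 1%", {
  topo <- list(
    atoms = tibble::tibble(name = c("A", "B"), element = c("C", "C"),
                           mass = c(12, 12), charge = c(0, 0),
                           sigma = c(3.4, 3.4), epsilon = c(0, 0)),
    bonds = tibble::tibble(i = 1, j = 2, r0 = 1.5, k = 1000))
  sys <- build_system(topo)
  mu <- 6  # reduced mass, u
  period <- 2 * pi * sqrt(mu / (1000 * 100))  # ps; factor 100: unit conversion
  dt <- period / 100
  x0 <- rbind(c(-0.8, 0, 0), c(0.8, 0, 0))   # stretched by 0.1 A
  conf <- conformation(x0)
  # distance trace: measure the oscillation period from successive maxima
  nst <- 400
  dists <- numeric(nst)
  c2 <- conf
  for (s in seq_len(nst)) {
    c2 <- integrate_step(sys, c2, dt)
    dists[s] <- sqrt(sum((c2$xyz[1, ] - c2$xyz[2, ])^2))
  }
  # count full periods between first and last maximum of (r - r0)
  ext <- which(diff(sign(diff(dists))) == -2) + 1
  measured <- mean(diff(ext)) * dt
  expect_lt(abs(measured - period) / period, 0.01)
})

test_that("zero forces give uniform straight-line motion", {
  topo <- list(
    atoms = tibble::tibble(name = c("A", "B"), element = c("C", "C"),
                           mass = c(12, 12), charge = c(0, 0),
                           sigma = c(3.4, 3.4), epsilon = c(0, 0)),
    bonds = tibble::tibble(i = 1, j = 2, r0 = 2, k = 500))
  sys <- build_system(topo)
  x0 <- rbind(c(0, 0, 0), c(2, 0, 0))        # bond at equilibrium
  v0 <- rbind(c(0.1, 0.2, 0), c(0.1, 0.2, 0))  # pure translation
  res <- integrate_dynamics(sys, conformation(x0, v0), 0.001, 1000)
  expect_equal(res$conf$xyz, x0 + v0 * 1, tolerance = 1e-9)
})

test_that("NVE total energy shows no secular drift (< 0.1% of mean KE)", {
  toy <- toy_fixture()
  set.seed(3)
  conf <- conformation(toy$conformation$xyz,
                       draw_velocities(toy$system, 313))
  res <- integrate_dynamics(toy$system, conf, 5e-4, 10000)
  drift <- abs(mean(utils::tail(res$etot, 1000)) -
                 mean(utils::head(res$etot, 1000)))
  expect_lt(drift / mean(res$ekin), 0.001)
})

test_that("empty constraint set reduces run_mdoc to plain thermostatted MD", {
  toy <- toy_fixture()
  cfg <- mdoc_config(duration = 0.01, dt = 5e-4, snapshot = 1, drop = 2,
                     tau = 5, rho = 5, seed = 4)
  traj <- run_mdoc(toy$system, toy$conformation, list(), cfg)
  expect_gt(length(traj$times), 0)
  expect_equal(nrow(traj$book$rdc), 0)
  # identical to the bare integrator under the same initial velocities
  set.seed(4)
  v0 <- draw_velocities(toy$system, 313)
  res <- integrate_dynamics(toy$system, conformation(toy$conformation$xyz, v0),
                            5e-4, 20L,
                            thermostat = list(temperature = 313, tau = 0.5))
  cfg2 <- mdoc_config(duration = 0.001, dt = 5e-4, snapshot = 0.01,
                      drop = 0.005, tau = 5, rho = 5, seed = 4)
  traj2 <- run_mdoc(toy$system, toy$conformation, list(), cfg2)
  expect_equal(traj2$coords[[1]], res$conf$xyz, tolerance = 1e-10)
})

test_that("snapshot count follows floor((duration - drop)/interval)", {
  toy <- toy_fixture()
  cfg <- mdoc_config(duration = 0.01, dt = 5e-4, snapshot = 0.2, drop = 4,
                     tau = 5, rho = 5, seed = 1)
  traj <- run_mdoc(toy$system, toy$conformation, list(), cfg)
  expect_lte(abs(length(traj$times) - floor((10 - 4) / 0.2)), 1)
  expect_true(all(diff(traj$times) > 0))
})

test_that("pseudo-forces vanish when experimental values equal the means", {
  toy <- toy_fixture()
  x <- toy$conformation$xyz
  # memory mean tensor equal to the experimental target tensor -> every
  # tanh factor is zero
  F0 <- rdc_pseudo_force(x, c(2, 7), exp_tensor(3), d_exp = 3,
                         d_max = 191.84, width = 0.5, k = 1)
  expect_lt(max(abs(F0)), 1e-10)
  Fn <- noe_pseudo_force(x, c(7, 8), rbar = 2.8, r_exp = 2.8,
                         width = 0.25, k = 30)
  expect_lt(max(abs(Fn)), 1e-10)
  Fj <- j_pseudo_force(x, c(7, 2, 3, 8), j_mean = 4.2, j_exp = 4.2,
                       width = 0.5, k = 2)
  expect_lt(max(abs(Fj)), 1e-10)
})

test_that("snapshot averages equal recomputation from the update log", {
  toy <- toy_fixture()
  tabs <- tables_fixture()
  cfg <- mdoc_config(duration = 0.005, dt = 5e-4, snapshot = 1e-3, drop = 1e-3,
                     tau = 2, rho = 2, seed = 3, record_log = TRUE)
  traj <- run_mdoc(toy$system, toy$conformation, tabs, cfg)
  dt <- cfg$dt
  decay <- exp(-dt / cfg$tau)
  nstep <- nrow(traj$log$rdc)
  snap_steps <- round(traj$times / dt)
  # recompute the exponential mean of the first RDC zz component
  log_zz <- traj$log$rdc[, 9]
  S <- 0; N <- 0
  recomputed <- numeric(length(snap_steps))
  for (s in seq_len(nstep)) {
    S <- S * decay + log_zz[s] * dt
    N <- N * decay + dt
    hit <- which(snap_steps == s)
    if (length(hit)) recomputed[hit] <- S / N
  }
  expect_equal(recomputed, traj$rdc_mean[, 9], tolerance = 1e-8)
  # same for a NOE pair and a 3J coupling
  log_r6 <- traj$log$noe[, 1]
  S <- 0; N <- 0
  rec_noe <- numeric(length(snap_steps))
  for (s in seq_len(nstep)) {
    S <- S * decay + log_r6[s] * dt
    N <- N * decay + dt
    hit <- which(snap_steps == s)
    if (length(hit)) rec_noe[hit] <- (S / N)^(-1 / 6)
  }
  expect_equal(rec_noe, traj$noe_mean[, 1], tolerance = 1e-8)
})

test_that("identical seed and config replay bitwise-identical trajectories", {
  toy <- toy_fixture()
  tabs <- tables_fixture()
  cfg <- mdoc_config(duration = 0.01, dt = 5e-4, snapshot = 1, drop = 5,
                     tau = 5, rho = 5, seed = 9)
  t1 <- run_mdoc(toy$system, toy$conformation, tabs, cfg)
  t2 <- run_mdoc(toy$system, toy$conformation, tabs, cfg)
  expect_identical(t1$times, t2$times)
  expect_equal(t1$coords[[length(t1$coords)]],
               t2$coords[[length(t2$coords)]], tolerance = 1e-12)
  cfg3 <- mdoc_config(duration = 0.01, dt = 5e-4, snapshot = 1, drop = 5,
                      tau = 5, rho = 5, seed = 10)
  t3 <- run_mdoc(toy$system, toy$conformation, tabs, cfg3)
  expect_false(isTRUE(all.equal(t1$coords[[length(t1$coords)]],
                                t3$coords[[length(t3$coords)]])))
})

test_that("constraints referencing missing atoms fail before any dynamics", {
  toy <- toy_fixture()
  bad <- list(noe = noe_table("x", 7, 99, target = 3, error = 0.5))
  cfg <- mdoc_config(duration = 0.01, dt = 5e-4, snapshot = 1, drop = 5,
                     tau = 5, rho = 5)
  expect_error(run_mdoc(toy$system, toy$conformation, bad, cfg),
               "missing atom")
})
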