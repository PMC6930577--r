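#' MDOC run configuration
#'
#' Collects every tunable of a restrained run. Times are in ps unless noted.
#'
#' @param duration total simulated time, ns.
#' @param dt integration time step, ps (0.5 fs default: safe for C-H
#'   stretches at the thermostat target).
#' @param temperature thermostat target, K.
#' @param tau memory time of the exponential average, ps.
#' @param rho rise time of the pseudo-force ramp `1 - exp(-t/rho)`, ps;
#'   defaults to `tau`.
#' @param s_am alignment-medium order parameter scaling static splittings
#'   into the residual regime, dimensionless in (0, 1].
#' @param k_rdc,k_noe,k_j pseudo-force constants per constraint class
#'   (kJ mol^-1 per Hz, at saturation kJ mol^-1 A^-1, and kJ mol^-1 per Hz);
#'   defaults calibrated on the synthetic single-rotor recovery benchmark.
#' @param snapshot snapshot interval, ps.
#' @param drop equilibration period excluded from snapshots, ps.
#' @param tau_thermostat Berendsen coupling time, ps.
#' @param seed master seed for initial velocities.
#' @param record_log keep the per-step observable log (short diagnostic
#'   runs only; memory grows linearly with steps).
#' @return object of class `mdoc_config`.
#' @export
mdoc_config <- function(duration = 2, dt = 5e-4, temperature = 313,
                        tau = 200, rho = tau, s_am = 0.004,
                        k_rdc = 0.12, k_noe = 60, k_j = 6,
                        snapshot = 5, drop = 1000, tau_thermostat = 0.5,
                        seed = 1, record_log = FALSE) {
  stopifnot(dt > 0, tau > 0, rho > 0, s_am > 0, s_am <= 1,
            snapshot >= dt, duration > 0, temperature > 0)
  if (drop >= duration * 1000) stop("drop must be shorter than the run")
  structure(list(duration = duration, dt = dt, temperature = temperature,
                 tau = tau, rho = rho, s_am = s_am,
                 k_rdc = k_rdc, k_noe = k_noe, k_j = k_j,
                 snapshot = snapshot, drop = drop,
                 tau_thermostat = tau_thermostat, seed = seed,
                 record_log = record_log),
            class = "mdoc_config")
}

#' Maxwell-Boltzmann initial velocities
#'
#' Per-component sd is `10 sqrt(kB T / m)` A/ps; the centre-of-mass
#' momentum is removed. Drawn from R's RNG, so reproducible under
#' `set.seed()`.
#'
#' @param system a `molecular_system`.
#' @param temperature K.
#' @return n x 3 velocity matrix, A/ps.
#' @export
draw_velocities <- function(system, temperature) {
  m <- system$atoms$mass
  n <- length(m)
  v <- matrix(stats::rnorm(3 * n), n, 3) * (10 * sqrt(.kB * temperature / m))
  p <- colSums(v * m) / sum(m)
  sweep(v, 2, p)
}

#' Velocity-Verlet integration without constraints
#'
#' Plain thermostatted (or NVE) dynamics on the classical force field;
#' exposed mainly for validation of the integrator.
#'
#' @param system a `molecular_system`.
#' @param conf starting `conformation`.
#' @param dt time step, ps.
#' @param nsteps number of steps.
#' @param thermostat `NULL` for NVE, else `list(temperature =, tau =)`.
#' @return list with final `conformation`, per-step total energy `etot` and
#'   kinetic energy `ekin` (kJ/mol).
#' @export
integrate_dynamics <- function(system, conf, dt, nsteps, thermostat = NULL) {
  res <- cpp_verlet_steps(conf$xyz, conf$vel, system$compiled, dt,
                          as.integer(nsteps), !is.null(thermostat),
                          if (is.null(thermostat)) 0 else thermostat$temperature,
                          if (is.null(thermostat)) 1 else thermostat$tau)
  list(conf = conformation(res$x, res$v, conf$time + nsteps * dt),
       etot = res$etot, ekin = res$ekin)
}

#' Single integration step
#'
#' One velocity-Verlet step (see [integrate_dynamics()]).
#' @inheritParams integrate_dynamics
#' @return the advanced `conformation`.
#' @export
integrate_step <- function(system, conf, dt, thermostat = NULL) {
  integrate_dynamics(system, conf, dt, 1L, thermostat)$conf
}

#' Run a restrained MDOC simulation
#'
#' At every step the classical forces are augmented with ramped
#' pseudo-forces from each RDC, NOE and 3J constraint; force magnitudes
#' come from the exponential-memory averaged deviation (means as of the
#' previous step), directions from the instantaneous geometry. Snapshots
#' (coordinates plus memory-averaged observables) are recorded at the
#' configured interval after the equilibration drop.
#'
#' @param system a `molecular_system`.
#' @param start starting `conformation` (velocities ignored; drawn from
#'   `config$seed`).
#' @param constraints list with elements `rdc`, `noe`, `j` — tibbles in the
#'   formats produced by [synthesize_constraints()] / read by
#'   [read_constraint_tables()]. Any element may be missing.
#' @param config an [mdoc_config()].
#' @return object of class `mdoc_trajectory`.
#' @export
run_mdoc <- function(system, start, constraints, config) {
  stopifnot(inherits(system, "molecular_system"),
            inherits(start, "conformation"),
            inherits(config, "mdoc_config"))
  comp <- compile_constraints(system, constraints, config, start)
  set.seed(config$seed)
  v0 <- draw_velocities(system, config$temperature)
  nsteps <- as.integer(round(config$duration * 1000 / config$dt))
  cfg <- list(dt = config$dt, nsteps = nsteps,
              drop_steps = as.integer(round(config$drop / config$dt)),
              snap_every = as.integer(round(config$snapshot / config$dt)),
              temp = config$temperature, tau_t = config$tau_thermostat,
              tau = config$tau, rho = config$rho,
              k_rdc = config$k_rdc, k_noe = config$k_noe, k_j = config$k_j,
              thermostat = TRUE, record_log = config$record_log)
  res <- cpp_run_mdoc(start$xyz, v0, system$compiled, comp$cons, cfg)
  structure(list(times = res$times, coords = res$coords,
                 energies = res$energies,
                 rdc_mean = res$rdc_mean, noe_mean = res$noe_mean,
                 j_mean = res$j_mean, mem = res$mem, log = res$log,
                 x_final = res$x_final, v_final = res$v_final,
                 book = comp$book, config = config, system = system,
                 seed = config$seed),
            class = "mdoc_trajectory")
}

#' @export
print.mdoc_trajectory <- function(x, ...) {
  cat("<mdoc_trajectory> ", length(x$times), " snapshots over ",
      if (length(x$times)) paste0(min(x$times), "-", max(x$times)) else "0",
      " ps; constraints: ", nrow(x$book$rdc), " RDC, ",
      nrow(x$book$noe), " NOE, ", nrow(x$book$j), " 3J\n", sep = "")
  invisible(x)
}

#' Memory-averaged observables of a trajectory
#'
#' One row per snapshot and constraint: the exponentially averaged value of
#' the observable carried in the snapshot (RDC zz component in Hz, NOE
#' rbar in A, 3J in Hz).
#'
#' @param x an `mdoc_trajectory`.
#' @param ... unused.
#' @return tibble with `time`, `type`, `id`, `value`.
#' @method tidy mdoc_trajectory
#' @export
tidy.mdoc_trajectory <- function(x, ...) {
  out <- list()
  bk <- x$book
  if (nrow(bk$rdc)) {
    zz <- x$rdc_mean[, 9 * seq_len(nrow(bk$rdc)), drop = FALSE]
    out$rdc <- tibble::tibble(
      time = rep(x$times, times = ncol(zz)),
      type = rep(bk$rdc$type, each = length(x$times)),
      id = rep(bk$rdc$id, each = length(x$times)),
      value = as.vector(zz))
  }
  if (nrow(bk$noe)) {
    # pool expanded methyl pairs back to one datum via r^-6
    r6 <- x$noe_mean^-6
    agg <- sapply(split(seq_len(nrow(bk$noe_pairs)), bk$noe_pairs$datum),
                  function(ix) rowMeans(r6[, ix, drop = FALSE]))
    agg <- matrix(agg, nrow = length(x$times))^(-1 / 6)
    out$noe <- tibble::tibble(
      time = rep(x$times, times = ncol(agg)),
      type = "NOE",
      id = rep(bk$noe$id, each = length(x$times)),
      value = as.vector(agg))
  }
  if (nrow(bk$j)) {
    out$j <- tibble::tibble(
      time = rep(x$times, times = ncol(x$j_mean)),
      type = "3J",
      id = rep(bk$j$id, each = length(x$times)),
      value = as.vector(x$j_mean))
  }
  dplyr::bind_rows(out)
}

#' Quality of a trajectory against its constraints
#'
#' The reported theoretical value of each datum is the mean over retained
#' snapshots of its memory-averaged observable (the running ensemble value),
#' compared to the experimental value with its error.
#'
#' @param traj an `mdoc_trajectory`.
#' @return a quality report tibble, see [quality_report()].
#' @export
trajectory_quality <- function(traj) {
  bk <- traj$book
  rows <- list()
  if (nrow(bk$rdc)) {
    zz <- traj$rdc_mean[, 9 * seq_len(nrow(bk$rdc)), drop = FALSE]
    rows$rdc <- tibble::tibble(type = bk$rdc$type, id = bk$rdc$id,
                               theo = colMeans(zz), exp = bk$rdc$d_exp,
                               err = bk$rdc$error)
  }
  if (nrow(bk$noe)) {
    r6 <- traj$noe_mean^-6
    theo <- vapply(split(seq_len(nrow(bk$noe_pairs)), bk$noe_pairs$datum),
                   function(ix) mean(r6[, ix]), numeric(1))^(-1 / 6)
    rows$noe <- tibble::tibble(type = "NOE", id = bk$noe$id, theo = theo,
                               exp = bk$noe$target, err = bk$noe$error)
  }
  if (nrow(bk$j)) {
    rows$j <- tibble::tibble(type = "3J", id = bk$j$id,
                             theo = colMeans(traj$j_mean),
                             exp = bk$j$j_exp, err = bk$j$error)
  }
  quality_report(dplyr::bind_rows(rows))
}

#' @method glance mdoc_trajectory
#' @export
glance.mdoc_trajectory <- function(x, ...) {
  q <- trajectory_quality(x)
  dplyr::filter(q, .data$type == "overall")
}

#' Convergence plot of memory-averaged observables
#'
#' Traces the exponentially averaged observables across snapshots, one
#' facet per constraint type, with the experimental targets as horizontal
#' reference lines.
#'
#' @param object an `mdoc_trajectory`.
#' @param ids optional subset of constraint ids.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mdoc_trajectory
#' @export
autoplot.mdoc_trajectory <- function(object, ids = NULL, ...) {
  d <- tidy.mdoc_trajectory(object)
  if (!is.null(ids)) d <- dplyr::filter(d, .data$id %in% ids)
  bk <- object$book
  targets <- dplyr::bind_rows(
    if (nrow(bk$rdc)) tibble::tibble(type = bk$rdc$type, id = bk$rdc$id, exp = bk$rdc$d_exp),
    if (nrow(bk$noe)) tibble::tibble(type = "NOE", id = bk$noe$id, exp = bk$noe$target),
    if (nrow(bk$j)) tibble::tibble(type = "3J", id = bk$j$id, exp = bk$j$j_exp))
  if (!is.null(ids)) targets <- dplyr::filter(targets, .data$id %in% ids)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value,
                                  colour = .data$id)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::geom_hline(data = targets,
                        ggplot2::aes(yintercept = .data$exp, colour = .data$id),
                        linetype = 2, show.legend = FALSE) +
    ggplot2::facet_wrap(~type, scales = "free_y") +
    ggplot2::labs(x = "time (ps)", y = "memory-averaged observable")
}
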