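#' Simulation configuration
#'
#' Bundles and validates the run parameters of the Langevin replica-exchange
#' engine.  Times are in the reduced unit tau_L = sigma * sqrt(m/epsilon);
#' temperatures are in k_B T / epsilon.
#'
#' @param temperatures temperature ladder (k_B T / epsilon), strictly
#'   increasing.  The production ladder spans 1.0 to 1.63 over 18 replicas;
#'   [temperature_ladder()] builds a geometric ladder.
#' @param h integration time step (tau_L units; default 0.005).
#' @param zeta friction coefficient (m / tau_L; low-friction default 0.05).
#' @param box cubic box edge in Angstrom (default 1140); `NA` disables
#'   periodicity.
#' @param phi_c crowder volume fraction in `[0, 0.55)`.
#' @param exchange_interval time between exchange attempts (tau_L; default
#'   400).
#' @param sample_interval steps between recorded frames (default 1000).
#' @param max_steps total integration steps per replica.
#' @param seed RNG seed; every source of randomness in the run flows from it.
#' @param store_positions keep per-frame coordinates (memory-heavy).
#' @param frozen_crowders if `TRUE` crowders do not move.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(temperatures, h = 0.005, zeta = 0.05,
                              box = 1140, phi_c = 0,
                              exchange_interval = 400,
                              sample_interval = 1000,
                              max_steps = 10000, seed = 1,
                              store_positions = TRUE,
                              frozen_crowders = FALSE) {
  if (h <= 0) stop("parameter error: h must be > 0")
  if (any(diff(temperatures) <= 0)) {
    stop("parameter error: temperature ladder must be strictly increasing")
  }
  if (phi_c < 0 || phi_c >= 0.55) {
    stop("parameter error: phi_c must be in [0, 0.55)")
  }
  structure(list(
    temperatures = temperatures, h = h, zeta = zeta, box = box,
    phi_c = phi_c, exchange_interval = exchange_interval,
    sample_interval = sample_interval, max_steps = max_steps, seed = seed,
    store_positions = store_positions, frozen_crowders = frozen_crowders
  ), class = "simulation_config")
}

#' Geometric temperature ladder
#'
#' @param n number of replicas (default 18).
#' @param t_min,t_max ladder ends in k_B T / epsilon (defaults 1.0 and 1.63).
#' @return numeric vector of length `n`, geometrically spaced.
#' @export
temperature_ladder <- function(n = 18, t_min = 1.0, t_max = 1.63) {
  t_min * (t_max / t_min)^(seq(0, 1, length.out = n))
}

#' Place hard-sphere crowders in a periodic box
#'
#' Inserts `N = floor(phi_c * box^3 / ((4/3) pi R^3))` non-overlapping
#' spheres under the minimum-image convention.  Dilute systems use random
#' sequential insertion; above `phi_c` = 0.2 (where sequential insertion
#' becomes impractically slow and eventually jams) placement switches to a
#' jittered simple-cubic lattice, which is deterministic per seed and
#' overlap-free by construction.
#'
#' @param phi_c volume fraction.
#' @param box cubic box edge (Angstrom).
#' @param radius crowder radius (55 Angstrom for Ficoll 70).
#' @param seed RNG seed.
#' @param max_attempts insertion attempts per sphere before giving up.
#' @return N x 3 matrix of centres within `[0, box)`, attribute `radius`.
#' @export
place_crowders <- function(phi_c, box, radius = 55, seed = 1,
                           max_attempts = 20000) {
  n <- floor(phi_c * box^3 / ((4 / 3) * pi * radius^3))
  out <- matrix(numeric(0), 0, 3)
  if (n > 0) {
    set.seed(seed)
    if (phi_c <= 0.2) {
      out <- matrix(NA_real_, n, 3)
      placed <- 0
      attempts <- 0
      while (placed < n) {
        cand <- stats::runif(3, 0, box)
        ok <- TRUE
        if (placed > 0) {
          d <- .min_image(sweep(out[seq_len(placed), , drop = FALSE], 2, cand),
                          box)
          ok <- all(rowSums(d * d) >= (2 * radius)^2)
        }
        if (ok) {
          placed <- placed + 1
          out[placed, ] <- cand
          attempts <- 0
        } else {
          attempts <- attempts + 1
          if (attempts > max_attempts) {
            stop("crowder insertion failed after ", max_attempts,
                 " attempts; lower phi_c")
          }
        }
      }
    } else {
      n_side <- ceiling(n^(1 / 3))
      spacing <- box / n_side
      if (spacing < 2 * radius) {
        stop("phi_c = ", phi_c, " infeasible: lattice spacing ", spacing,
             " below crowder diameter; lower phi_c")
      }
      jit <- (spacing - 2 * radius) / 2
      grid <- as.matrix(expand.grid(seq_len(n_side), seq_len(n_side),
                                    seq_len(n_side)))
      sites <- (grid - 0.5) * spacing
      pick <- sample(nrow(sites), n)
      out <- sites[pick, , drop = FALSE] +
        matrix(stats::runif(3 * n, -jit, jit), n, 3)
      out <- out %% box
    }
  }
  dimnames(out) <- NULL
  attr(out, "radius") <- radius
  out
}

#' Append crowder beads to a topology
#'
#' @param top a `cg_topology`.
#' @param centres matrix from [place_crowders()].
#' @param radius crowder radius (taken from `centres` if present).
#' @param box box edge stored on the topology.
#' @param mass crowder mass in reduced units.  Kept of the same order as the
#'   bead mass so crowder motion stays on the protein time scale.
#' @return topology with CROWDER beads and `box` set.
#' @export
add_crowders <- function(top, centres, radius = attr(centres, "radius") %||% 55,
                         box = NA, mass = 10) {
  if (length(centres) && nrow(centres)) {
    n0 <- nrow(top$beads)
    cb <- data.frame(
      index = n0 + seq_len(nrow(centres)), kind = "CROWDER",
      resno = NA_integer_, resid = "CRW",
      x = centres[, 1], y = centres[, 2], z = centres[, 3],
      sigma = radius, mass = mass, charge = 0, stringsAsFactors = FALSE
    )
    top$beads <- rbind(top$beads, cb)
  }
  top$box <- box
  top
}

# ---------------------------------------------------------------------------
# dynamics systems: a uniform surface over coarse-grained topologies and
# analytic benchmark systems

#' Wrap a topology as a propagatable system
#'
#' Builds the cached pair lists and exposes `energy(pos)` / `forces(pos)`
#' closures plus masses, so the integrator and the replica-exchange driver
#' work identically on protein topologies and analytic benchmark systems.
#'
#' @param top a `cg_topology`.
#' @param params optional [electrostatics_params()].
#' @param f steric scaling factor.
#' @param mobile logical mask of beads that move (defaults to all; frozen
#'   crowders are handled here).
#' @return A `dynamics_system` list.
#' @export
as_dynamics_system <- function(top, params = NULL, f = 0.9, mobile = NULL) {
  pairs <- build_pair_lists(top)
  n <- nrow(top$beads)
  if (is.null(mobile)) mobile <- rep(TRUE, n)
  bonded <- unique(c(top$bonds$i, top$bonds$j))
  structure(list(
    n = n,
    masses = top$beads$mass,
    box = top$box,
    mobile = mobile,
    wrap = !(seq_len(n) %in% bonded) & top$beads$kind == "CROWDER",
    sigma_min = min(top$beads$sigma),
    energy = function(pos) total_energy(top, pos, params, pairs, f)$total,
    forces = function(pos) total_forces(top, pos, params, pairs, f)
  ), class = "dynamics_system")
}

# one BBK (velocity-Verlet with friction and noise) step; the random force
# has variance 2 zeta kT / h per degree of freedom and enters both half-kicks
.langevin_block <- function(system, pos, vel, kT, nsteps, h, zeta,
                            sample_every = Inf, sample_offset = 0) {
  m <- system$masses
  mobile <- system$mobile
  box <- system$box %||% NA
  noise_sd <- sqrt(2 * zeta * kT / h)
  half <- h / (2 * m)
  denom <- 1 + zeta * half
  F <- system$forces(pos)
  samples <- list()
  for (s in seq_len(nsteps)) {
    R <- matrix(stats::rnorm(length(pos), sd = noise_sd), ncol = 3)
    vhalf <- vel * (1 - zeta * half) + half * (F + R)
    vhalf[!mobile, ] <- 0
    disp <- h * vhalf
    if (max(abs(disp)) > 0.5 * (system$sigma_min %||% Inf)) {
      stop("integration instability: displacement exceeded half the ",
           "smallest bead radius in one step; reduce h")
    }
    pos <- pos + disp
    # wrap only unbonded beads (crowders): wrapping a bonded bead would
    # stretch its springs across the box; bonded distances are non-periodic
    if (is.finite(box) && any(system$wrap)) {
      pos[system$wrap, ] <- pos[system$wrap, , drop = FALSE] %% box
    }
    F <- system$forces(pos)
    vel <- (vhalf + half * (F + R)) / denom
    vel[!mobile, ] <- 0
    if (is.finite(sample_every) && (sample_offset + s) %% sample_every == 0) {
      samples[[length(samples) + 1]] <-
        list(step = sample_offset + s, pos = pos, energy = system$energy(pos))
    }
  }
  list(pos = pos, vel = vel, samples = samples)
}

#' Propagate one trajectory with low-friction Langevin dynamics
#'
#' @param system a `dynamics_system`.
#' @param pos starting positions (n x 3).
#' @param kT temperature in epsilon units.
#' @param nsteps number of steps.
#' @param h time step (tau_L).
#' @param zeta friction (m / tau_L).
#' @param vel starting velocities (default: Maxwell-Boltzmann at `kT`).
#' @param sample_every record a frame every this many steps (`Inf` = none).
#' @param seed optional seed (`NULL` keeps the current RNG stream).
#' @return list with final `pos`, `vel` and a `samples` list of
#'   `(step, pos, energy)` records.
#' @export
run_dynamics <- function(system, pos, kT, nsteps, h = 0.005, zeta = 0.05,
                         vel = NULL, sample_every = Inf, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(vel)) {
    vel <- matrix(stats::rnorm(length(pos), sd = sqrt(kT / system$masses)),
                  ncol = 3)
    vel[!system$mobile, ] <- 0
  }
  .langevin_block(system, pos, vel, kT, nsteps, h, zeta, sample_every)
}

#' Replica-exchange acceptance rule
#'
#' Probability of swapping two replicas with energies `e_i`, `e_j` at
#' inverse temperatures `beta_i`, `beta_j`:
#' \eqn{\min(1, \exp[(\beta_i - \beta_j)(E_i - E_j)])}.
#'
#' @param e_i,e_j potential energies (epsilon units).
#' @param beta_i,beta_j inverse temperatures (1/kT, epsilon units).
#' @return the acceptance probability.
#' @export
exchange_probability <- function(e_i, e_j, beta_i, beta_j) {
  min(1, exp((beta_i - beta_j) * (e_i - e_j)))
}

#' Run temperature replica-exchange Langevin dynamics
#'
#' Propagates one replica per ladder temperature, attempts exchanges between
#' alternating even/odd neighbour pairs at the configured interval, records
#' frames at the sampling cadence and logs per-pair acceptance statistics.
#' On acceptance the two replicas swap temperatures and their velocities are
#' rescaled by `sqrt(T_new / T_old)`.  All randomness flows from
#' `config$seed`.
#'
#' @param system a `dynamics_system`.
#' @param pos0 starting positions, shared by all replicas (n x 3) or a list
#'   of per-replica matrices.
#' @param config a [simulation_config()].
#' @return A `replica_ensemble`: list with `frames` (data.frame: `step`,
#'   `replica`, `temp_index`, `temperature`, `energy`), `positions` (list of
#'   frame coordinate matrices, parallel to `frames`, when
#'   `store_positions`), `exchange` (per neighbour pair: attempts, accepts),
#'   and the `config`.
#' @export
run_rem <- function(system, pos0, config) {
  set.seed(config$seed)
  temps <- config$temperatures
  nrep <- length(temps)
  h <- config$h
  ex_steps <- max(1L, round(config$exchange_interval / h))
  n_blocks <- max(1L, floor(config$max_steps / ex_steps))

  if (!is.list(pos0)) pos0 <- replicate(nrep, pos0, simplify = FALSE)
  reps <- lapply(seq_len(nrep), function(k) {
    vel <- matrix(stats::rnorm(length(pos0[[k]]),
                               sd = sqrt(temps[k] / system$masses)), ncol = 3)
    vel[!system$mobile, ] <- 0
    list(pos = pos0[[k]], vel = vel, tidx = k)
  })

  frames <- list()
  positions <- list()
  ex_attempts <- ex_accepts <- integer(nrep - 1)

  for (blk in seq_len(n_blocks)) {
    offset <- (blk - 1L) * ex_steps
    energies <- numeric(nrep)
    for (k in seq_len(nrep)) {
      st <- .langevin_block(system, reps[[k]]$pos, reps[[k]]$vel,
                            temps[reps[[k]]$tidx], ex_steps, h, config$zeta,
                            config$sample_interval, offset)
      reps[[k]]$pos <- st$pos
      reps[[k]]$vel <- st$vel
      for (sm in st$samples) {
        frames[[length(frames) + 1]] <- data.frame(
          step = sm$step, replica = k, temp_index = reps[[k]]$tidx,
          temperature = temps[reps[[k]]$tidx], energy = sm$energy)
        if (config$store_positions) {
          positions[[length(positions) + 1]] <- sm$pos
        }
      }
      energies[k] <- system$energy(reps[[k]]$pos)
      if (!is.finite(energies[k])) {
        stop("non-finite energy in replica ", k, " at block ", blk)
      }
    }
    # alternate even/odd neighbour pairs in temperature order
    start <- if (blk %% 2 == 1) 1L else 2L
    if (start > nrep - 1L) next
    holder <- integer(nrep)                # temp index -> replica
    for (k in seq_len(nrep)) holder[reps[[k]]$tidx] <- k
    for (t1 in seq(start, nrep - 1L, by = 2L)) {
      t2 <- t1 + 1L
      ki <- holder[t1]; kj <- holder[t2]
      p <- exchange_probability(energies[ki], energies[kj],
                                1 / temps[t1], 1 / temps[t2])
      ex_attempts[t1] <- ex_attempts[t1] + 1L
      if (stats::runif(1) < p) {
        ex_accepts[t1] <- ex_accepts[t1] + 1L
        reps[[ki]]$tidx <- t2
        reps[[kj]]$tidx <- t1
        reps[[ki]]$vel <- reps[[ki]]$vel * sqrt(temps[t2] / temps[t1])
        reps[[kj]]$vel <- reps[[kj]]$vel * sqrt(temps[t1] / temps[t2])
        holder[t1] <- kj; holder[t2] <- ki
      }
    }
  }

  frames <- if (length(frames)) do.call(rbind, frames) else
    data.frame(step = integer(), replica = integer(), temp_index = integer(),
               temperature = numeric(), energy = numeric())
  structure(list(
    frames = frames, positions = positions,
    exchange = data.frame(pair = paste(seq_len(nrep - 1), 2:nrep, sep = "-"),
                          attempts = ex_attempts, accepts = ex_accepts,
                          ratio = ifelse(ex_attempts > 0,
                                         ex_accepts / pmax(1, ex_attempts),
                                         NA_real_)),
    config = config
  ), class = "replica_ensemble")
}

#' @export
print.replica_ensemble <- function(x, ...) {
  cat("<replica_ensemble> ", nrow(x$frames), " frames, ",
      length(x$config$temperatures), " replicas\n", sep = "")
  print(x$exchange)
  invisible(x)
}

#' Integrated autocorrelation time of the sampled energies
#'
#' A cadence diagnostic: frames separated by more than about twice this
#' number of sampling intervals can be treated as uncorrelated.
#'
#' @param ensemble a `replica_ensemble`.
#' @param temp_index which ladder temperature to analyse.
#' @return estimated integrated autocorrelation time, in frames.
#' @export
energy_autocorrelation_time <- function(ensemble, temp_index = 1) {
  e <- ensemble$frames$energy[ensemble$frames$temp_index == temp_index]
  if (length(e) < 10) return(NA_real_)
  a <- stats::acf(e, plot = FALSE, lag.max = min(length(e) - 1, 200))$acf[-1]
  cut <- which(a < 0.05)[1]
  if (!is.na(cut)) a <- a[seq_len(cut)]
  max(0.5, 0.5 + sum(a))
}
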