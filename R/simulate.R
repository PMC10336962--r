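#' Bead-necklace simulation configuration
#'
#' Collects every parameter of the bead-necklace Monte Carlo model. Defaults
#' follow the model's published parametrization: hard-sphere bead radius
#' 2 Angstrom, harmonic bonds with equilibrium distance 4.1 Angstrom and
#' force constant 0.4 N/m, a uniform soft short-range attraction of 0.6 kT at
#' closest contact, extended Debye-Hueckel electrostatics, explicit
#' counterions (one per chain charge, radius 2 Angstrom), single-particle
#' moves 17 times more probable than each of the pivot, chain-translation and
#' slithering moves, and 200,000 equilibration plus 1,000,000 production
#' cycles. One cycle is one attempted move per mobile particle.
#'
#' @param bead_radius hard-sphere radius of chain beads, Angstrom
#' @param ion_radius hard-sphere radius of counterions, Angstrom
#' @param bond_r0 bond equilibrium distance, Angstrom
#' @param bond_force_constant harmonic force constant, N/m
#' @param attraction_contact depth of the chain-chain attraction at closest
#'   contact, kT (the potential is -eps * (sigma/r)^6 with sigma twice the
#'   bead radius, so the stated depth is reached exactly at contact)
#' @param salt_mM 1:1 salt concentration, mM (enters through the screening
#'   length only; counterions are explicit)
#' @param temperature_K absolute temperature, K
#' @param relative_permittivity solvent relative permittivity
#' @param box_side cubic box side, Angstrom; `NULL` (default) picks 1.1 times
#'   the chain contour length at run time
#' @param move_weights relative weights of the four move classes, named
#'   `single_bead`, `pivot`, `chain_translate`, `slither`; counterion
#'   translations share the single-particle class
#' @param max_displacement per-move amplitudes, named `bead`, `ion`, `chain`
#'   (Angstrom) and `theta_max` (radians, pivot rotation half-range)
#' @param n_equil_cycles equilibration cycles (discarded)
#' @param n_prod_cycles production cycles
#' @param sample_interval cycles between samples of Rg and energy
#' @param n_store_frames maximum number of coordinate frames retained
#' @return a `bn_config` list
#' @export
bn_config <- function(bead_radius = 2.0, ion_radius = 2.0,
                      bond_r0 = 4.1, bond_force_constant = 0.4,
                      attraction_contact = 0.6,
                      salt_mM = 0, temperature_K = 298,
                      relative_permittivity = 78.4,
                      box_side = NULL,
                      move_weights = c(single_bead = 17, pivot = 1,
                                       chain_translate = 1, slither = 1),
                      max_displacement = c(bead = 1.5, ion = 5.0,
                                           chain = 2.0, theta_max = pi / 2),
                      n_equil_cycles = 200000, n_prod_cycles = 1000000,
                      sample_interval = 100, n_store_frames = 50) {
  stopifnot(bead_radius > 0, ion_radius > 0, bond_r0 > 0,
            bond_force_constant > 0, salt_mM >= 0, temperature_K > 0,
            all(move_weights >= 0), move_weights[["single_bead"]] > 0,
            n_equil_cycles >= 0, n_prod_cycles >= 0)
  if (relative_permittivity <= 0)
    stop("relative permittivity must be > 0")
  structure(list(bead_radius = bead_radius, ion_radius = ion_radius,
                 bond_r0 = bond_r0,
                 bond_force_constant = bond_force_constant,
                 attraction_contact = attraction_contact,
                 salt_mM = salt_mM, temperature_K = temperature_K,
                 relative_permittivity = relative_permittivity,
                 box_side = box_side, move_weights = move_weights,
                 max_displacement = max_displacement,
                 n_equil_cycles = n_equil_cycles,
                 n_prod_cycles = n_prod_cycles,
                 sample_interval = sample_interval,
                 n_store_frames = n_store_frames),
            class = "bn_config")
}

#' Debye-Hueckel screening parameters
#'
#' Bjerrum length lambda_B = e^2 / (4 pi eps0 eps_r kB T) and inverse Debye
#' screening length kappa, with kappa^2 = 8 pi lambda_B n for a 1:1 salt of
#' number density n. Zero salt gives kappa = 0 exactly (unscreened Coulomb).
#'
#' @inheritParams bn_config
#' @return list with `bjerrum_length` (Angstrom) and `inverse_debye_length`
#'   (1/Angstrom)
#' @examples
#' debye_parameters(150)   # lambda_B ~ 7.1 A, 1/kappa ~ 7.9 A at 298 K
#' @export
debye_parameters <- function(salt_mM, temperature_K = 298,
                             relative_permittivity = 78.4) {
  stopifnot(salt_mM >= 0, temperature_K > 0)
  if (relative_permittivity <= 0)
    stop("relative permittivity must be > 0")
  lB_m <- .const$e^2 /
    (4 * pi * .const$eps0 * relative_permittivity * .const$kB * temperature_K)
  lB <- lB_m * 1e10  # Angstrom
  n_A3 <- salt_mM * 1e-3 * .const$N_A * 1e-27  # ions of each sign per A^3
  kappa <- sqrt(8 * pi * lB * n_A3)
  list(bjerrum_length = lB, inverse_debye_length = kappa)
}

# harmonic bond force constant in kT/A^2
.bond_k_kT <- function(config) {
  config$bond_force_constant * 1e-20 / (.const$kB * config$temperature_K)
}

#' Harmonic bond energy
#'
#' U = (k/2) (r - r0)^2 with the force constant converted from N/m to
#' kT/Angstrom^2 at the configured temperature (0.4 N/m is about
#' 0.97 kT/Angstrom^2 at 298 K).
#'
#' @param r bond length(s), Angstrom
#' @param config a [bn_config()]
#' @return energy in kT
#' @export
bond_energy <- function(r, config = bn_config()) {
  stopifnot(all(r > 0))
  0.5 * .bond_k_kT(config) * (r - config$bond_r0)^2
}

#' Non-bonded pair energy
#'
#' Extended Debye-Hueckel interaction between two charges of hard-sphere
#' radii a_i, a_j,
#' U = lambda_B z_i z_j exp(-kappa (r - a_i - a_j)) /
#' (r (1 + kappa a_i)(1 + kappa a_j)), plus, for chain-chain pairs only, the
#' uniform soft attraction -eps (sigma/r)^6 with sigma the contact distance.
#' Center distances below the contact distance are hard-core overlaps and
#' return `Inf`.
#'
#' @param r center-center distance(s), Angstrom, > 0
#' @param z_i,z_j integer charges
#' @param kind `"chain_chain"`, `"chain_ion"` or `"ion_ion"`
#' @param config a [bn_config()]
#' @return energy in kT (`Inf` marks hard overlap)
#' @examples
#' pair_energy(4, 0, 0, "chain_chain")   # -0.6 kT at closest contact
#' @export
pair_energy <- function(r, z_i, z_j,
                        kind = c("chain_chain", "chain_ion", "ion_ion"),
                        config = bn_config()) {
  kind <- match.arg(kind)
  stopifnot(all(r > 0))
  a_i <- if (kind == "ion_ion") config$ion_radius else config$bead_radius
  a_j <- if (kind == "chain_chain") config$bead_radius else config$ion_radius
  dh <- debye_parameters(config$salt_mM, config$temperature_K,
                         config$relative_permittivity)
  lB <- dh$bjerrum_length; kap <- dh$inverse_debye_length
  contact <- a_i + a_j
  n <- max(length(r), length(z_i), length(z_j))
  r <- rep_len(r, n); z_i <- rep_len(z_i, n); z_j <- rep_len(z_j, n)
  u <- ifelse(z_i == 0 | z_j == 0, 0,
              lB * z_i * z_j * exp(-kap * (r - a_i - a_j)) /
                (r * (1 + kap * a_i) * (1 + kap * a_j)))
  if (kind == "chain_chain") {
    sigma <- 2 * config$bead_radius
    u <- u - config$attraction_contact * (sigma / r)^6
  }
  u[r < contact] <- Inf
  u
}

#' Total system energy (reference implementation)
#'
#' Direct double loop over all particle pairs under the minimum image
#' convention, plus all bond terms. This is the plain O(n^2) reference path
#' used to validate the compiled simulation engine's incremental energy
#' bookkeeping; it is intentionally written without shortcuts.
#'
#' @param state list with `chain` (n x 3 matrix, Angstrom), `ions` (m x 3
#'   matrix or NULL), `bead_charge`, `ion_charge` (integer vectors)
#' @param config a [bn_config()]; `config$box_side` must be set
#' @return total energy in kT; `Inf` if any hard-core overlap
#' @export
total_energy <- function(state, config) {
  box <- config$box_side
  if (is.null(box)) stop("config$box_side must be set for total_energy")
  chain <- state$chain
  ions <- state$ions
  if (is.null(ions)) ions <- matrix(numeric(0), 0, 3)
  n <- nrow(chain); m <- nrow(ions)
  pos <- rbind(chain, ions)
  z <- c(state$bead_charge, if (m) state$ion_charge else integer(0))
  is_chain <- c(rep(TRUE, n), rep(FALSE, m))

  mi_dist <- function(i, j) {
    d <- pos[i, ] - pos[j, ]
    d <- d - box * round(d / box)
    sqrt(sum(d^2))
  }
  u <- 0
  for (i in seq_len(n + m - 1)) {
    for (j in (i + 1):(n + m)) {
      r <- mi_dist(i, j)
      kind <- if (is_chain[i] && is_chain[j]) "chain_chain"
              else if (!is_chain[i] && !is_chain[j]) "ion_ion"
              else "chain_ion"
      u <- u + pair_energy(r, z[i], z[j], kind, config)
      if (!is.finite(u)) return(Inf)
    }
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      d <- pos[i, ] - pos[i + 1, ]
      d <- d - box * round(d / box)
      u <- u + bond_energy(sqrt(sum(d^2)), config)
    }
  }
  u
}

#' Metropolis acceptance rule
#'
#' Accepts a trial move with probability min(1, exp(-dU/kT)): non-positive
#' energy changes are always accepted, hard overlaps (`dU = Inf`) always
#' rejected. Vectorized; each element draws its own uniform variate.
#'
#' @param delta_u energy change(s) in kT
#' @return logical vector of acceptances
#' @export
metropolis_accept <- function(delta_u) {
  delta_u <= 0 | stats::runif(length(delta_u)) < exp(-delta_u)
}

# grow a self-avoiding random walk with fixed bond length; bounded retries
.init_chain <- function(n_beads, config, box) {
  r0 <- config$bond_r0
  min_d <- 2 * config$bead_radius
  for (attempt in seq_len(200)) {
    pos <- matrix(NA_real_, n_beads, 3)
    pos[1, ] <- runif(3, 0, box)
    ok <- TRUE
    for (i in seq_len(n_beads - 1)) {
      placed <- FALSE
      for (try in seq_len(100)) {
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        cand <- pos[i, ] + r0 * dir
        d <- sweep(pos[seq_len(i), , drop = FALSE], 2, cand)
        d <- d - box * round(d / box)
        if (min(sqrt(rowSums(d^2))) >= min_d) {
          pos[i + 1, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pos)
  }
  stop("could not place a non-overlapping starting chain; ",
       "try a larger box_side")
}

.init_ions <- function(n_ions, chain, config, box) {
  if (n_ions == 0L) return(matrix(numeric(0), 0, 3))
  ions <- matrix(NA_real_, n_ions, 3)
  for (i in seq_len(n_ions)) {
    placed <- FALSE
    for (try in seq_len(2000)) {
      cand <- runif(3, 0, box)
      others <- rbind(chain, ions[seq_len(i - 1), , drop = FALSE])
      d <- sweep(others, 2, cand)
      d <- d - box * round(d / box)
      r <- sqrt(rowSums(d^2))
      lim <- c(rep(config$bead_radius + config$ion_radius, nrow(chain)),
               rep(2 * config$ion_radius, i - 1))
      if (all(r >= lim)) { ions[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place counterion ", i, "; try a larger box_side")
  }
  ions
}

#' Run a bead-necklace Monte Carlo simulation
#'
#' Canonical-ensemble Metropolis sampling of a charged hard-sphere bead chain
#' with explicit counterions (one per chain charge, of opposite sign). The
#' starting chain is a self-avoiding random walk at the bond equilibrium
#' length; counterions are placed uniformly at random without overlap.
#' Equilibration cycles are discarded; during production the chain radius of
#' gyration (unweighted over chain beads), squared end-to-end distance and
#' the running total energy are sampled every `sample_interval` cycles.
#'
#' @param charges a `charge_assignment` from [assign_charges()], a sequence
#'   string (charges assigned at pH 7), or an integer vector of per-bead
#'   charges in \{-1, 0, +1\}
#' @param config a [bn_config()]
#' @param seed integer seed; identical seed and config reproduce the run
#'   bit-for-bit
#' @return a `bn_trajectory`: list with `rg_series`, `ree2_series`,
#'   `energy_series`, `sample_cycle` (Angstrom / kT / cycles), `frames`
#'   (retained coordinate snapshots with their running energies),
#'   `acceptance` (per-move-type attempted/accepted counts), `energy_drift`
#'   (running minus recomputed total energy at run end), `min_pair_distance`
#'   (smallest center-center distance seen in any sampled frame), the
#'   resolved `config`, `bead_charge`, `ion_charge`, `box_side` and `seed`
#' @examples
#' \donttest{
#' traj <- run_bead_necklace(assign_charges("KKDDAAAAAA"),
#'                           bn_config(salt_mM = 150, n_equil_cycles = 500,
#'                                     n_prod_cycles = 2000,
#'                                     sample_interval = 10),
#'                           seed = 1)
#' mean(traj$rg_series)
#' }
#' @export
run_bead_necklace <- function(charges, config = bn_config(), seed = 1) {
  if (is.character(charges)) charges <- assign_charges(charges)
  if (inherits(charges, "charge_assignment"))
    charges <- charges$per_bead_charge
  charges <- as.integer(charges)
  if (any(abs(charges) > 1L)) stop("per-bead charges must be in {-1, 0, +1}")
  n <- length(charges)
  if (n < 2L) stop("chain must have at least 2 beads")

  box <- config$box_side
  if (is.null(box)) box <- 1.1 * (n - 1) * config$bond_r0
  if (box < (n - 1) * config$bond_r0)
    stop("box_side must be at least the chain contour length")

  ion_charge <- as.integer(-charges[charges != 0L])
  dh <- debye_parameters(config$salt_mM, config$temperature_K,
                         config$relative_permittivity)

  res <- .with_seed(seed, {
    chain0 <- .init_chain(n, config, box)
    ions0 <- .init_ions(length(ion_charge), chain0, config, box)
    .mc_run_cpp(chain0, ions0, charges, ion_charge,
                box, config$bead_radius, config$ion_radius,
                config$bond_r0, .bond_k_kT(config),
                config$attraction_contact, 2 * config$bead_radius,
                dh$bjerrum_length, dh$inverse_debye_length,
                as.integer(config$n_equil_cycles),
                as.integer(config$n_prod_cycles),
                as.integer(config$sample_interval),
                config$max_displacement[["bead"]],
                config$max_displacement[["ion"]],
                config$max_displacement[["chain"]],
                config$max_displacement[["theta_max"]],
                as.numeric(config$move_weights[c("single_bead", "pivot",
                                                 "chain_translate",
                                                 "slither")]),
                as.integer(config$n_store_frames))
  })

  acc <- data.frame(move_type = res$move_type,
                    attempted = res$attempted, accepted = res$accepted)
  acc$fraction <- ifelse(acc$attempted > 0, acc$accepted / acc$attempted, NA)
  cfg <- config; cfg$box_side <- box
  structure(list(rg_series = res$rg_series, ree2_series = res$ree2_series,
                 energy_series = res$energy_series,
                 sample_cycle = res$sample_cycle,
                 frames = res$frames, acceptance = acc,
                 energy_drift = res$energy_running - res$energy_recomputed,
                 min_pair_distance = res$min_pair_distance,
                 chain_final = res$chain_final, ions_final = res$ions_final,
                 bead_charge = charges, ion_charge = ion_charge,
                 box_side = box, config = cfg, seed = seed),
            class = "bn_trajectory")
}

#' @export
print.bn_trajectory <- function(x, ...) {
  cat(sprintf(
    "Bead-necklace trajectory: %d beads, %d counterions, %d samples (seed %s)\n",
    length(x$bead_charge), length(x$ion_charge), length(x$rg_series),
    format(x$seed)))
  if (length(x$rg_series))
    cat(sprintf("  mean Rg %.2f Angstrom (sd %.2f), mean energy %.2f kT\n",
                mean(x$rg_series), stats::sd(x$rg_series),
                mean(x$energy_series)))
  invisible(x)
}

#' @export
summary.bn_trajectory <- function(object, n_blocks = 10, ...) {
  rg <- object$rg_series
  ba <- block_average(rg, n_blocks)
  cat(sprintf(
    "Bead-necklace run: %d beads, %d ions, salt %.0f mM, box %.0f Angstrom\n",
    length(object$bead_charge), length(object$ion_charge),
    object$config$salt_mM, object$box_side))
  cat(sprintf("  Rg = %.2f +/- %.2f Angstrom (block s.e., %d samples)\n",
              ba$mean, ba$se, length(rg)))
  cat(sprintf("  statistical inefficiency %.1f, energy drift %.2e kT\n",
              statistical_inefficiency(rg), object$energy_drift))
  cat("  acceptance fractions:\n")
  a <- object$acceptance
  for (i in seq_len(nrow(a)))
    if (a$attempted[i] > 0)
      cat(sprintf("    %-16s %.2f\n", a$move_type[i], a$fraction[i]))
  invisible(object)
}

#' @export
plot.bn_trajectory <- function(x, ...) {
  plot(x$sample_cycle, x$rg_series, type = "l", xlab = "production cycle",
       ylab = "Rg (Angstrom)", ...)
  invisible(x)
}

#' Counterion radial distribution
#'
#' Distribution of the minimum-image distance from each counterion to its
#' nearest chain bead, histogrammed over all retained frames. Densities are
#' normalized to unit integral; raw bin counts are kept so occupancy
#' conservation can be checked. Hard-sphere exclusion leaves zero density
#' below the bead-ion contact distance.
#'
#' @param trajectory a `bn_trajectory` with at least one counterion and at
#'   least 10 retained frames
#' @param bin_width histogram bin width, Angstrom
#' @param split_by_sign also return separate distributions for +1 and -1
#'   counterions
#' @return list with `breaks`, `mids`, `counts`, `density`, and when
#'   `split_by_sign` the per-sign equivalents plus per-sign mean minimum
#'   distances
#' @export
counterion_rdf <- function(trajectory, bin_width = 1, split_by_sign = TRUE) {
  if (!length(trajectory$ion_charge))
    stop("trajectory has no counterions")
  frames <- trajectory$frames
  if (length(frames) < 10L)
    stop("need at least 10 retained frames (increase n_store_frames)")
  box <- trajectory$box_side
  mind <- function(frame) {
    chain <- frame$chain; ions <- frame$ions
    vapply(seq_len(nrow(ions)), function(i) {
      d <- sweep(chain, 2, ions[i, ])
      d <- d - box * round(d / box)
      min(sqrt(rowSums(d^2)))
    }, numeric(1))
  }
  dists <- lapply(frames, mind)
  all_d <- unlist(dists)
  sign_d <- rep(trajectory$ion_charge, times = length(frames))
  breaks <- seq(0, max(all_d) + bin_width, by = bin_width)
  hist_of <- function(v) {
    counts <- as.numeric(table(cut(v, breaks, include.lowest = TRUE)))
    list(counts = counts,
         density = counts / (sum(counts) * bin_width))
  }
  h <- hist_of(all_d)
  out <- list(breaks = breaks, mids = breaks[-1] - bin_width / 2,
              counts = h$counts, density = h$density,
              n_observations = length(all_d))
  if (split_by_sign) {
    for (sgn in c(1L, -1L)) {
      v <- all_d[sign_d == sgn]
      if (!length(v)) next
      key <- if (sgn > 0) "positive" else "negative"
      hh <- hist_of(v)
      out[[paste0("counts_", key)]] <- hh$counts
      out[[paste0("density_", key)]] <- hh$density
      out[[paste0("mean_min_distance_", key)]] <- mean(v)
    }
  }
  out
}

#' Block average of a correlated series
#'
#' @param x numeric series
#' @param n_blocks number of equal blocks
#' @return list with `mean`, `se` (standard error of the block means) and
#'   `block_means`
#' @export
block_average <- function(x, n_blocks = 10) {
  n <- length(x)
  if (n < n_blocks) n_blocks <- max(1L, n)
  size <- n %/% n_blocks
  bm <- vapply(seq_len(n_blocks),
               function(b) mean(x[((b - 1) * size + 1):(b * size)]),
               numeric(1))
  se <- if (n_blocks > 1) stats::sd(bm) / sqrt(n_blocks) else 0
  list(mean = mean(bm), se = se, block_means = bm)
}

#' Statistical inefficiency of a sampled series
#'
#' g = 1 + 2 sum_t (1 - t/n) rho_t, with the autocorrelation sum truncated at
#' the first non-positive estimate. The effective number of independent
#' samples is length(x)/g; for an AR(1) process with coefficient phi the
#' exact value is (1 + phi)/(1 - phi).
#'
#' @param x numeric series
#' @return statistical inefficiency, >= 1 (1 for uncorrelated or constant
#'   series)
#' @export
statistical_inefficiency <- function(x) {
  n <- length(x)
  if (n < 3L || stats::var(x) == 0) return(1)
  rho <- stats::acf(x, lag.max = min(n - 2L, 10000L), plot = FALSE,
                    demean = TRUE)$acf[-1]
  pos <- which(rho <= 0)
  upto <- if (length(pos)) pos[1] - 1L else length(rho)
  if (upto < 1L) return(1)
  t <- seq_len(upto)
  max(1, 1 + 2 * sum((1 - t / n) * rho[t]))
}

#' Convergence diagnostics across replicate runs
#'
#' Block-averaged mean Rg with standard error per replicate, the statistical
#' inefficiency of each series, the cross-replicate mean and spread, and
#' flags for replicates whose means sit further from the grand mean than
#' `flag_threshold` pooled standard errors (the signature of a replicate
#' trapped in a local minimum).
#'
#' @param trajectories a `bn_trajectory`, or list of them, or list of
#'   numeric Rg series
#' @param n_blocks blocks per replicate for [block_average()]
#' @param flag_threshold flagging multiple of the pooled standard error
#' @return a `bn_convergence` list: `replicates` data frame (mean, se,
#'   statistical inefficiency, flagged), `grand_mean`, `spread` (sd of
#'   replicate means), `pooled_se`
#' @export
convergence_report <- function(trajectories, n_blocks = 10,
                               flag_threshold = 3) {
  if (inherits(trajectories, "bn_trajectory"))
    trajectories <- list(trajectories)
  series <- lapply(trajectories, function(t)
    if (inherits(t, "bn_trajectory")) t$rg_series else as.numeric(t))
  if (!length(series)) stop("need at least one replicate")
  ba <- lapply(series, block_average, n_blocks = n_blocks)
  means <- vapply(ba, `[[`, numeric(1), "mean")
  ses <- vapply(ba, `[[`, numeric(1), "se")
  g <- vapply(series, statistical_inefficiency, numeric(1))
  grand <- mean(means)
  pooled_se <- sqrt(mean(ses^2))
  flagged <- abs(means - grand) > flag_threshold * pooled_se
  structure(list(
    replicates = data.frame(replicate = seq_along(series), mean = means,
                            se = ses, stat_ineff = g, flagged = flagged),
    grand_mean = grand,
    spread = if (length(means) > 1) stats::sd(means) else 0,
    pooled_se = pooled_se,
    flag_threshold = flag_threshold), class = "bn_convergence")
}

#' @export
print.bn_convergence <- function(x, ...) {
  cat(sprintf("Convergence over %d replicate(s): Rg %.2f +/- %.2f Angstrom\n",
              nrow(x$replicates), x$grand_mean, x$pooled_se))
  print(x$replicates, row.names = FALSE, digits = 4)
  if (any(x$replicates$flagged))
    cat("flagged replicate(s): ",
        paste(x$replicates$replicate[x$replicates$flagged], collapse = ", "),
        " (beyond ", x$flag_threshold, " pooled s.e.)\n", sep = "")
  invisible(x)
}

#' Write a trajectory as plain-text XYZ plus a CSV sidecar
#'
#' Frames are written in XYZ format, chain beads first then counterions,
#' with element tags encoding the charge (`BP`/`B0`/`BN` for beads,
#' `IP`/`IN` for ions); the per-sample Rg/energy series go to a CSV file
#' alongside, and the configuration to a YAML header file.
#'
#' @param trajectory a `bn_trajectory`
#' @param prefix output path prefix; writes `<prefix>.xyz`, `<prefix>.csv`,
#'   `<prefix>.yaml`
#' @return invisibly, the paths written
#' @export
write_trajectory <- function(trajectory, prefix) {
  xyz <- paste0(prefix, ".xyz")
  tag <- function(z, chain) {
    if (chain) c("BN", "B0", "BP")[z + 2L] else c("IN", "I0", "IP")[z + 2L]
  }
  con <- file(xyz, "w"); on.exit(close(con), add = TRUE)
  for (f in trajectory$frames) {
    nat <- nrow(f$chain) + nrow(f$ions)
    writeLines(c(as.character(nat),
                 sprintf("cycle %d energy_kT %.6f", as.integer(f$cycle),
                         f$energy)), con)
    for (i in seq_len(nrow(f$chain)))
      writeLines(sprintf("%s %.4f %.4f %.4f",
                         tag(trajectory$bead_charge[i], TRUE),
                         f$chain[i, 1], f$chain[i, 2], f$chain[i, 3]), con)
    for (i in seq_len(nrow(f$ions)))
      writeLines(sprintf("%s %.4f %.4f %.4f",
                         tag(trajectory$ion_charge[i], FALSE),
                         f$ions[i, 1], f$ions[i, 2], f$ions[i, 3]), con)
  }
  csv <- paste0(prefix, ".csv")
  utils::write.csv(data.frame(cycle = trajectory$sample_cycle,
                              rg = trajectory$rg_series,
                              ree2 = trajectory$ree2_series,
                              energy = trajectory$energy_series),
                   csv, row.names = FALSE)
  yml <- paste0(prefix, ".yaml")
  cfg <- trajectory$config
  cfg$move_weights <- as.list(cfg$move_weights)
  cfg$max_displacement <- as.list(cfg$max_displacement)
  yaml::write_yaml(c(unclass(cfg), list(seed = trajectory$seed)), yml)
  invisible(c(xyz = xyz, csv = csv, yaml = yml))
}
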