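#' Generate an IDP-like sequence with prescribed composition
#'
#' Builds a random sequence whose descriptors hit exact targets: fraction of
#' charged residues (FCR), net charge per residue (NCPR), proline fraction,
#' and optionally the mean Kyte-Doolittle hydropathy. Positive residues are
#' drawn from \{K, R\}, negative from \{D, E\}; histidine is never used, so
#' the charge targets are exact at pH 7. Neutral filler residues are chosen
#' by a greedy match to the hydropathy target followed by single-residue swap
#' refinement, then the whole sequence is shuffled. Deterministic per seed.
#'
#' @param length sequence length, >= 1
#' @param target_fcr target fraction of charged residues; `length *
#'   target_fcr` must be a whole number
#' @param target_ncpr target net charge per residue, <= `target_fcr`;
#'   `length * target_ncpr` must be whole and of the same parity as the
#'   charged count
#' @param target_kd optional target mean Kyte-Doolittle hydropathy; `NULL`
#'   leaves the filler composition unconstrained
#' @param proline_fraction target proline fraction; `length *
#'   proline_fraction` must be whole
#' @param seed integer seed
#' @param net_charge_sign sign of the net charge, `+1` (default) or `-1`
#' @return an amino-acid string whose [sequence_descriptors()] match the
#'   targets. FCR, NCPR and the proline fraction are met exactly; the KD mean
#'   is met to about 1/length (at worst 1.1/length, the half-width of the
#'   largest gap in the neutral-residue hydropathy alphabet, reached only
#'   when a single filler residue must bridge the glycine-alanine gap)
#' @examples
#' s <- make_sequence(10, target_fcr = 0.3, target_ncpr = 0.1, seed = 1)
#' sequence_descriptors(s)$fcr    # 0.3
#' @export
make_sequence <- function(length, target_fcr = 0, target_ncpr = 0,
                          target_kd = NULL, proline_fraction = 0,
                          seed = 1, net_charge_sign = 1) {
  stopifnot(length >= 1, target_fcr >= 0, target_fcr <= 1,
            target_ncpr >= 0, net_charge_sign %in% c(-1, 1))
  if (target_ncpr > target_fcr + 1e-9)
    stop("target_ncpr must not exceed target_fcr")
  n_charged <- target_fcr * length
  n_net <- target_ncpr * length
  n_pro <- proline_fraction * length
  near <- function(x) abs(x - round(x)) < 1e-9
  if (!near(n_charged) || !near(n_net) || !near(n_pro))
    stop(sprintf(
      "composition not achievable at length %d; nearest achievable: fcr %.4g, ncpr %.4g, proline %.4g",
      length, round(n_charged) / length, round(n_net) / length,
      round(n_pro) / length))
  n_charged <- round(n_charged); n_net <- round(n_net); n_pro <- round(n_pro)
  if ((n_charged + n_net) %% 2 != 0)
    stop(sprintf(
      "fcr and ncpr targets need charged and net counts of equal parity; nearest achievable ncpr: %.4g or %.4g",
      max(0, n_net - 1) / length, min(n_charged, n_net + 1) / length))
  n_plus <- (n_charged + n_net) %/% 2
  n_minus <- n_charged - n_plus
  if (net_charge_sign < 0) { tmp <- n_plus; n_plus <- n_minus; n_minus <- tmp }
  n_fill <- length - n_charged - n_pro
  if (n_fill < 0)
    stop("charged + proline residues exceed the sequence length")

  .with_seed(seed, {
    plus <- sample(c("K", "R"), n_plus, replace = TRUE)
    minus <- sample(c("D", "E"), n_minus, replace = TRUE)
    pro <- rep("P", n_pro)
    fill <- character(0)
    kd <- kyte_doolittle()
    # neutral, non-titratable, non-proline candidates
    cand <- kd[c("A", "G", "S", "T", "N", "Q", "M", "F", "W", "I", "L", "V")]
    if (!is.null(target_kd)) {
      fixed_sum <- sum(kd[c(plus, minus, pro)])
      lo <- (fixed_sum + n_fill * min(cand)) / length
      hi <- (fixed_sum + n_fill * max(cand)) / length
      if (target_kd < lo - 1e-9 || target_kd > hi + 1e-9)
        stop(sprintf(
          "target_kd %.3g not achievable with this charge/proline composition; nearest achievable: %.3g",
          target_kd, if (target_kd < lo) lo else hi))
    }
    if (n_fill > 0) {
      if (is.null(target_kd)) {
        fill <- sample(names(cand), n_fill, replace = TRUE)
      } else {
        need <- target_kd * length - fixed_sum
        fill <- character(n_fill)
        remaining <- need
        for (i in seq_len(n_fill)) {
          want <- remaining / (n_fill - i + 1)
          pick <- names(cand)[which.min(abs(cand - want))]
          fill[i] <- pick
          remaining <- remaining - cand[[pick]]
        }
        # single-residue swap refinement of the filler multiset
        repeat {
          err <- sum(cand[fill]) - need
          best <- 0; bi <- 0; bc <- ""
          for (i in seq_len(n_fill)) {
            delta <- cand - cand[[fill[i]]]
            improve <- abs(err) - abs(err + delta)
            j <- which.max(improve)
            if (improve[j] > best + 1e-12) {
              best <- improve[j]; bi <- i; bc <- names(cand)[j]
            }
          }
          if (bi == 0) break
          fill[bi] <- bc
        }
        # pair-swap pass to escape single-swap local minima
        if (n_fill >= 2) repeat {
          err <- sum(cand[fill]) - need
          improved <- FALSE
          for (i in seq_len(n_fill - 1)) {
            di <- cand - cand[[fill[i]]]
            for (j in (i + 1):n_fill) {
              dj <- cand - cand[[fill[j]]]
              tot <- outer(di, dj, `+`)
              gain <- abs(err) - abs(err + tot)
              k <- which(gain == max(gain), arr.ind = TRUE)[1, ]
              if (gain[k[1], k[2]] > 1e-12) {
                fill[i] <- names(cand)[k[1]]
                fill[j] <- names(cand)[k[2]]
                err <- sum(cand[fill]) - need
                improved <- TRUE
              }
            }
          }
          if (!improved) break
        }
      }
    }
    paste(sample(c(plus, minus, pro, fill)), collapse = "")
  })
}

#' Generate a noisy power-law (N, Rg) dataset
#'
#' Chain lengths are sampled log-uniformly over the benchmark's range
#' \[24, 441\] and radii drawn from Rg = A N^nu exp(eps) with multiplicative
#' lognormal noise, eps ~ Normal(0, noise_sigma). Deterministic per seed.
#'
#' @param law a [scaling_law()]
#' @param n_points number of points, >= 3
#' @param noise_sigma standard deviation of the log-scale noise
#' @param seed integer seed
#' @param n_range range of chain lengths (default the benchmark's)
#' @return data frame with columns `n_residues` (integer) and `rg`
#' @export
make_power_law_dataset <- function(law, n_points, noise_sigma = 0.05,
                                   seed = 1, n_range = c(24, 441)) {
  stopifnot(inherits(law, "scaling_law"), n_points >= 3, noise_sigma >= 0)
  .with_seed(seed, {
    n <- round(exp(runif(n_points, log(n_range[1]), log(n_range[2]))))
    rg <- predict(law, n) * exp(rnorm(n_points, 0, noise_sigma))
    data.frame(n_residues = as.integer(n), rg = rg)
  })
}

# unnormalized radial Boltzmann density of a harmonic bond
.bond_density <- function(r, r0, k_kT) r^2 * exp(-0.5 * k_kT * (r - r0)^2)

#' Exact moments of the harmonic bond length distribution
#'
#' Mean squared bond length under the radial Boltzmann density
#' proportional to r^2 exp(-k (r - r0)^2 / 2), by quadrature. This is the
#' independent oracle for the simulator's phantom-chain limit: an ideal chain
#' of n beads with independent bonds has mean squared end-to-end distance
#' (n - 1) times this value.
#'
#' @param bond_r0 bond equilibrium distance, Angstrom
#' @param bond_force_constant force constant, N/m
#' @param temperature_K temperature, K
#' @return list with `mean_sq` (Angstrom^2) and `mean` (Angstrom)
#' @export
phantom_bond_moments <- function(bond_r0 = 4.1, bond_force_constant = 0.4,
                                 temperature_K = 298) {
  k_kT <- bond_force_constant * 1e-20 / (.const$kB * temperature_K)
  upper <- bond_r0 + 10 / sqrt(k_kT)
  z <- stats::integrate(.bond_density, 0, upper, r0 = bond_r0,
                        k_kT = k_kT)$value
  m1 <- stats::integrate(function(r) r * .bond_density(r, bond_r0, k_kT),
                         0, upper)$value / z
  m2 <- stats::integrate(function(r) r^2 * .bond_density(r, bond_r0, k_kT),
                         0, upper)$value / z
  list(mean_sq = m2, mean = m1)
}

#' Sample an ideal (phantom) bead chain
#'
#' Draws each bond length from the exact radial Boltzmann density of the
#' harmonic bond by inverse-CDF sampling on a fine grid, with directions
#' uniform on the sphere, and returns chain coordinates. Bond vectors are
#' independent, so chain statistics are known in closed form (see
#' [phantom_bond_moments()]).
#'
#' @param n_beads number of beads, >= 2
#' @param bond_r0 bond equilibrium distance, Angstrom
#' @param bond_force_constant force constant, N/m
#' @param temperature_K temperature, K
#' @param seed integer seed
#' @return `n_beads` x 3 coordinate matrix, Angstrom
#' @export
make_phantom_chain <- function(n_beads, bond_r0 = 4.1,
                               bond_force_constant = 0.4,
                               temperature_K = 298, seed = 1) {
  stopifnot(n_beads >= 2)
  k_kT <- bond_force_constant * 1e-20 / (.const$kB * temperature_K)
  sd_b <- 1 / sqrt(k_kT)
  grid <- seq(max(0, bond_r0 - 10 * sd_b), bond_r0 + 10 * sd_b,
              length.out = 4096)
  dens <- .bond_density(grid, bond_r0, k_kT)
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  .with_seed(seed, {
    b <- stats::approx(cdf, grid, runif(n_beads - 1), ties = "ordered",
                       rule = 2)$y
    dirs <- matrix(rnorm(3 * (n_beads - 1)), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pos <- rbind(c(0, 0, 0), apply(dirs * b, 2, cumsum))
    unname(pos)
  })
}
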