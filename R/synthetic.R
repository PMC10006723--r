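#' Conformational state templates
#'
#' Backbone dihedral templates (degrees) used by the synthetic generator:
#' \code{"helical"} places every residue pair at the alpha-helical
#' (phi, psi) = (-63.8, -38.3); \code{"extended"} at the beta/C5
#' (-157.2, 161.9); \code{"hairpin"} mixes the two along the chain (first
#' half helical, second half extended), mimicking a part-folded hairpin.
#'
#' @param name One of \code{"helical"}, \code{"extended"}, \code{"hairpin"}.
#' @param n_pairs Number of residue phi/psi pairs.
#' @return Numeric vector of length 2 * n_pairs (phi_1, psi_1, phi_2, ...).
#' @export
state_template <- function(name = c("helical", "extended", "hairpin"),
                           n_pairs = 18L) {
  name <- match.arg(name)
  helix <- c(-63.8, -38.3)
  ext <- c(-157.2, 161.9)
  per_pair <- switch(name,
    helical  = matrix(helix, nrow = n_pairs, ncol = 2L, byrow = TRUE),
    extended = matrix(ext, nrow = n_pairs, ncol = 2L, byrow = TRUE),
    hairpin  = {
      m <- matrix(helix, nrow = n_pairs, ncol = 2L, byrow = TRUE)
      half <- seq_len(n_pairs) > n_pairs / 2
      m[half, ] <- matrix(ext, nrow = sum(half), ncol = 2L, byrow = TRUE)
      m
    })
  as.vector(t(per_pair))
}

#' Specify a synthetic metastable-dynamics run
#'
#' Bundles everything the generator needs: per-state dihedral templates, a
#' Markov transition matrix over states, wrapped-Gaussian angular noise, a
#' state-dependent boost-energy model and the target unbiased populations
#' pi that exponential reweighting of the emitted frames should recover.
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes — metastable basins plus a non-negative bias — not any particular
#' MD engine's boost functional form.
#'
#' @param n_frames Frames to emit.
#' @param n_pairs Residue phi/psi pairs per frame (default 18, a 20-mer's
#'   interior residues).
#' @param templates List of per-state template vectors (see
#'   \code{\link{state_template}}); default the three shipped presets.
#' @param transition Row-stochastic state transition matrix; default a
#'   sticky uniform chain with 0.995 self-transition probability, giving
#'   metastable dwells of ~200 frames.
#' @param noise_sd Angular noise standard deviation, degrees; default 8.
#' @param target_pi Target unbiased state populations (sums to 1); default
#'   the chain's stationary distribution (no bias to undo).
#' @param boost_sd Standard deviation of the per-frame boost energy around
#'   its state mean, kcal/mol; default 0.05.
#' @param kT Thermal energy, kcal/mol.
#' @param stride_steps Stride metadata stamped on outputs.
#' @return Object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n_frames = 10000L, n_pairs = 18L,
                           templates = list(
                             helical  = state_template("helical", n_pairs),
                             extended = state_template("extended", n_pairs),
                             hairpin  = state_template("hairpin", n_pairs)),
                           transition = NULL, noise_sd = 8,
                           target_pi = NULL, boost_sd = 0.05,
                           kT = kT_kcal(), stride_steps = 1000L) {
  S <- length(templates)
  if (S < 1L) stop("need at least one state template")
  if (is.null(transition)) {
    transition <- matrix((1 - 0.995) / max(S - 1L, 1L), S, S)
    diag(transition) <- if (S > 1L) 0.995 else 1
  }
  transition <- as.matrix(transition)
  if (nrow(transition) != S || ncol(transition) != S) {
    stop("transition matrix must be ", S, " x ", S)
  }
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-10)) {
    stop("transition matrix rows must be non-negative and sum to 1")
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  p_stat <- stationary_distribution(transition)
  if (is.null(target_pi)) target_pi <- p_stat
  target_pi <- as.numeric(target_pi)
  if (length(target_pi) != S || any(target_pi < 0) ||
      abs(sum(target_pi) - 1) > 1e-10) {
    stop("target_pi must be a length-", S, " probability vector")
  }
  if (any(target_pi == 0 & p_stat > 0)) {
    stop("infeasible target: pi is zero where the chain has mass")
  }
  structure(list(n_frames = as.integer(n_frames), n_pairs = as.integer(n_pairs),
                 templates = templates, transition = transition,
                 noise_sd = noise_sd, target_pi = target_pi,
                 boost_sd = boost_sd, kT = kT,
                 stride_steps = as.integer(stride_steps),
                 p_stationary = p_stat),
            class = "synthetic_spec")
}

#' Stationary distribution of a row-stochastic matrix
#'
#' @param P Row-stochastic transition matrix.
#' @return Probability vector p with p P = p.
#' @export
stationary_distribution <- function(P) {
  eg <- eigen(t(P))
  i <- which.min(abs(eg$values - 1))
  v <- abs(Re(eg$vectors[, i]))
  v / sum(v)
}

#' Sample the hidden metastable state sequence
#'
#' Markov chain drawn from the spec's transition matrix, started from its
#' stationary distribution. Reproducible for a fixed seed.
#'
#' @param spec A \code{"synthetic_spec"}.
#' @param seed Integer RNG seed.
#' @return List with \code{states} (integer per-frame state), \code{dwell}
#'   (empirical dwell fractions) and \code{target_pi}.
#' @export
generate_states <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  S <- nrow(spec$transition)
  n <- spec$n_frames
  states <- integer(n)
  states[1L] <- sample.int(S, 1L, prob = spec$p_stationary)
  if (n > 1L) {
    u <- stats::runif(n - 1L)
    cum <- t(apply(spec$transition, 1L, cumsum))
    for (i in 2:n) {
      states[i] <- 1L + sum(u[i - 1L] > cum[states[i - 1L], ])
    }
  }
  list(states = states,
       dwell = tabulate(states, nbins = S) / n,
       target_pi = spec$target_pi)
}

#' Emit dihedral frames for a state sequence
#'
#' Each frame's angles are its state template plus independent Gaussian
#' noise (sd \code{spec$noise_sd} degrees), wrapped to (-180, 180].
#'
#' @param states Integer state sequence.
#' @param spec A \code{"synthetic_spec"}.
#' @param seed Integer RNG seed.
#' @return A \code{"dihedral_trajectory"}.
#' @export
states_to_dihedrals <- function(states, spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (max(states) > length(spec$templates)) {
    stop("state sequence references a missing template")
  }
  set.seed(seed)
  tmpl <- do.call(rbind, spec$templates)
  p <- ncol(tmpl)
  n <- length(states)
  ang <- tmpl[states, , drop = FALSE] +
    matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
  k <- spec$n_pairs
  labels <- as.vector(rbind(paste0("phi_", seq_len(k)),
                            paste0("psi_", seq_len(k))))
  dihedral_trajectory(ang, labels = labels, stride_steps = spec$stride_steps)
}

#' Emit a state-dependent boost series
#'
#' Per-frame boost dV_i = max(0, Normal(mean_state, boost_sd)). State means
#' are solved from the reweighting identity
#' p_b(s) exp(mean(s)/kT) proportional to pi(s), where p_b is the chain's
#' stationary distribution, then shifted so the smallest mean is 0 (the
#' shift cancels in normalised weights, and the boost stays non-negative).
#' Exponential reweighting of the emitted frames therefore targets pi.
#'
#' @param states Integer state sequence.
#' @param spec A \code{"synthetic_spec"}.
#' @param seed Integer RNG seed.
#' @return A \code{"boost_series"}.
#' @export
generate_boost <- function(states, spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  means <- boost_state_means(spec)
  mu <- means[states]
  dV <- pmax(0, stats::rnorm(length(states), mean = mu, sd = spec$boost_sd))
  boost_series(dV, stride_steps = spec$stride_steps)
}

#' Per-state boost means implied by the target populations
#'
#' @param spec A \code{"synthetic_spec"}.
#' @return Numeric vector of state boost means (kcal/mol, min 0).
#' @export
boost_state_means <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ok <- spec$p_stationary > 0
  m <- rep(0, length(spec$target_pi))
  m[ok] <- spec$kT * (log(spec$target_pi[ok]) - log(spec$p_stationary[ok]))
  m - min(m[ok])
}

#' Run the full synthetic generator
#'
#' Convenience wrapper producing the dihedral trajectory, boost series and
#' ground truth from one seed. Sub-seeds for the three draws are derived
#' deterministically from \code{seed}.
#'
#' @param spec A \code{"synthetic_spec"}.
#' @param seed Integer RNG seed governing all draws.
#' @return List with \code{trajectory}, \code{boost}, \code{truth}
#'   (states, dwell fractions, target pi, templates) and \code{seed}.
#' @export
simulate_trajectory <- function(spec = synthetic_spec(), seed = 1L) {
  st <- generate_states(spec, seed = seed)
  traj <- states_to_dihedrals(st$states, spec, seed = seed + 1L)
  boost <- generate_boost(st$states, spec, seed = seed + 2L)
  list(trajectory = traj, boost = boost,
       truth = list(states = st$states, dwell = st$dwell,
                    target_pi = spec$target_pi,
                    templates = spec$templates),
       seed = seed)
}
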