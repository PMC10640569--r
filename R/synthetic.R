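#' Specification of a synthetic developmental cohort
#'
#' Parameters for [generate_cohort()]. The generator emulates the
#' developmental contrast between distributed, redundant inter-module
#' connectivity (young subjects) and hub-concentrated connectivity with a
#' few strong inter-module bridges (older subjects), using a stochastic
#' block model whose inter-module wiring shifts continuously with age.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_nodes number of network nodes (>= 8).
#' @param n_modules number of modules/communities (>= 2).
#' @param age_range numeric length-2, age interval in years (default \[4, 19)).
#' @param hub_concentration_slope rate (per year) at which inter-module
#'   connectivity concentrates onto the fixed bridge set as age increases;
#'   0 removes any age dependence. Default `1/diff(age_range)` spans the
#'   full concentration range over the cohort ages.
#' @param edge_noise_sd standard deviation of multiplicative lognormal
#'   weight noise (>= 0).
#' @param hub_tilt strength of the within-module weight tilt toward the
#'   module hub at full concentration (older subjects' modules become
#'   hub-and-spoke; younger subjects' stay uniform).
#' @param p_within probability of a within-module edge.
#' @param p_inter_max probability of a non-bridge inter-module edge for the
#'   least hub-concentrated (youngest) subjects.
#' @param sphere_radius_mm radius of the sphere on which node coordinates
#'   are drawn (default 70 mm, head-sized).
#' @param master_seed integer master seed; per-subject seeds are derived
#'   from it by splitting and never reused.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 60, n_nodes = 60, n_modules = 4,
                        age_range = c(4, 19),
                        hub_concentration_slope = 1 / diff(range(age_range)),
                        edge_noise_sd = 0.15, hub_tilt = 1,
                        p_within = 0.85, p_inter_max = 0.35,
                        sphere_radius_mm = 70, master_seed = 1L) {
  if (n_subjects < 2) stop_config("n_subjects must be >= 2 (got %d)", n_subjects)
  if (n_nodes < 8) stop_config("n_nodes must be >= 8 (got %d)", n_nodes)
  if (n_modules < 2) stop_config("n_modules must be >= 2 (got %d)", n_modules)
  if (n_modules > n_nodes / 2) stop_config("n_modules too large for n_nodes")
  if (edge_noise_sd < 0) stop_config("edge_noise_sd must be >= 0")
  if (length(age_range) != 2 || diff(age_range) <= 0)
    stop_config("age_range must be an increasing length-2 interval")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_nodes = as.integer(n_nodes),
                 n_modules = as.integer(n_modules),
                 age_range = as.numeric(age_range),
                 hub_concentration_slope = hub_concentration_slope,
                 edge_noise_sd = edge_noise_sd, hub_tilt = hub_tilt,
                 p_within = p_within, p_inter_max = p_inter_max,
                 sphere_radius_mm = sphere_radius_mm,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

# Age -> bridge-concentration level in [0, 1]; slope = 0 gives a constant.
concentration_level <- function(spec, age) {
  mid <- mean(spec$age_range)
  pmin(1, pmax(0, 0.5 + spec$hub_concentration_slope * (age - mid)))
}

#' Generate a synthetic cohort of subjects with weighted connectomes
#'
#' Each subject receives covariates (age uniform over `age_range`, sex and
#' handedness at frequencies typical of developmental MEG cohorts) and a
#' weighted adjacency from a stochastic block model. One designated "hub"
#' node per module carries the fixed bridge edges (all hub pairs). As age
#' increases (with positive `hub_concentration_slope`), the number of
#' redundant non-bridge inter-module edges falls while the bridge weights
#' rise, preserving the expected total inter-module edge weight, so older
#' subjects depend on a few strong bridges and fragment earlier under
#' centrality-targeted attack.
#'
#' Node coordinates are drawn once per cohort on a sphere; the per-subject
#' radius grows mildly with age (emulating head growth), making the mean
#' node distance covariate non-degenerate.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `synthetic_cohort`: list with `covariates`
#'   (data.frame: id, age_years, sex, handedness, mean_node_distance, seed)
#'   and `connectomes` (list of [connectome()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  N <- spec$n_nodes
  module <- rep(seq_len(spec$n_modules), length.out = N)
  module <- sort(module)
  hubs <- match(seq_len(spec$n_modules), module)  # first node of each module

  base_coords <- with_seed(derive_seed(spec$master_seed, 0L), {
    z <- matrix(rnorm(N * 3), N, 3)
    z / sqrt(rowSums(z^2))
  })

  pair_i <- rep(seq_len(N - 1), times = (N - 1):1)
  pair_j <- unlist(lapply(seq_len(N - 1), function(i) (i + 1):N))
  same_mod <- module[pair_i] == module[pair_j]
  is_bridge <- (pair_i %in% hubs) & (pair_j %in% hubs)
  inter_nb <- !same_mod & !is_bridge          # non-bridge inter-module pairs
  n_inter_nb <- sum(inter_nb)
  n_bridge <- sum(is_bridge)
  hub_touch <- same_mod & ((pair_i %in% hubs) | (pair_j %in% hubs))
  n_hub_within <- sum(hub_touch)
  n_within <- sum(same_mod)

  w_within <- 1.0
  w_inter <- 1.0
  w_bridge0 <- 1.1  # slightly above within-module so bridges survive thresholding

  covs <- vector("list", spec$n_subjects)
  conns <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    seed_s <- derive_seed(spec$master_seed, s)
    res <- with_seed(seed_s, {
      age <- runif(1, spec$age_range[1], spec$age_range[2])
      sex <- sample(c("male", "female"), 1, prob = c(0.451, 0.549))
      hand <- sample(c("right", "left", "no_preference"), 1,
                     prob = c(0.878, 0.037, 0.085))
      conc <- concentration_level(spec, age)

      p_inter <- spec$p_inter_max * (1 - conc)
      # preserve expected total inter-module weight as edges concentrate
      shifted <- n_inter_nb * spec$p_inter_max * conc * w_inter
      w_bridge <- w_bridge0 + shifted / n_bridge

      # within-module weights tilt toward the module hub with age while the
      # expected total within-module weight stays fixed
      tilt <- spec$hub_tilt * conc
      w_hub <- w_within * (1 + tilt)
      w_spoke <- w_within * (n_within - n_hub_within * (1 + tilt)) /
        (n_within - n_hub_within)
      w_spoke <- max(w_spoke, 0.05 * w_within)

      w <- numeric(length(pair_i))
      keep_within <- runif(n_within) < spec$p_within
      w[same_mod][keep_within] <- ifelse(hub_touch[same_mod][keep_within],
                                         w_hub, w_spoke)
      keep_inter <- runif(n_inter_nb) < p_inter
      w[inter_nb][keep_inter] <- w_inter
      w[is_bridge] <- w_bridge
      nz <- w > 0
      if (spec$edge_noise_sd > 0)
        w[nz] <- w[nz] * exp(rnorm(sum(nz), 0, spec$edge_noise_sd))

      radius <- spec$sphere_radius_mm *
        (1 + 0.01 * (age - mean(spec$age_range)) + rnorm(1, 0, 0.03))
      coords <- base_coords * radius
      list(age = age, sex = sex, hand = hand, w = w, coords = coords)
    })
    W <- matrix(0, N, N)
    W[cbind(pair_i, pair_j)] <- res$w
    W <- W + t(W)
    conn <- connectome(W, node_coords = res$coords,
                       subject_id = sprintf("sub%03d", s))
    covs[[s]] <- data.frame(id = conn$subject_id,
                            age_years = res$age,
                            sex = res$sex,
                            handedness = res$hand,
                            mean_node_distance = conn$mean_distance,
                            seed = seed_s,
                            stringsAsFactors = FALSE)
    conns[[s]] <- conn
  }
  structure(list(covariates = do.call(rbind, covs),
                 connectomes = conns,
                 module = module, hubs = hubs, spec = spec),
            class = "synthetic_cohort")
}

#' Simulate phase-coupled oscillator recordings
#'
#' Fixture generator for wPLI validation: every node receives independent
#' unit-variance Gaussian noise scaled by `1/snr`; each coupling
#' `(i, j, freq_Hz, phase_lag_rad, snr)` adds a shared unit-RMS sinusoid at
#' `freq_Hz` with a fresh random phase per trial, node `j` lagging node `i`
#' by `phase_lag_rad`. Infinite `snr` yields noiseless sinusoids; uncoupled
#' nodes carry pure unit noise.
#'
#' @param n_nodes number of nodes.
#' @param coupling list of couplings, each a list or vector with elements
#'   `i, j, freq_Hz, phase_lag_rad, snr`.
#' @param n_trials number of trials.
#' @param fs sampling rate (Hz).
#' @param duration_s trial duration (s), default 2 (epoch length).
#' @param seed integer seed.
#' @return a [node_timeseries()].
#' @export
simulate_coupled_oscillators <- function(n_nodes, coupling = list(),
                                         n_trials = 50, fs = 250,
                                         duration_s = 2, seed = 1L) {
  if (duration_s <= 0) stop("duration_s must be positive")
  for (cp in coupling) {
    cp <- as.list(cp)
    if (cp$freq_Hz <= 0 || cp$freq_Hz >= fs / 2)
      stop("coupling frequency must lie in (0, fs/2)")
    if (cp$i < 1 || cp$j < 1 || cp$i > n_nodes || cp$j > n_nodes)
      stop("coupling node index out of range")
  }
  n_samp <- round(fs * duration_s)
  tt <- (0:(n_samp - 1)) / fs
  coupled <- unique(unlist(lapply(coupling, function(cp) c(cp$i, cp$j))))
  with_seed(seed, {
    data <- array(rnorm(n_trials * n_nodes * n_samp),
                  dim = c(n_trials, n_nodes, n_samp))
    # coupled nodes: noise enters at 1/snr relative to the unit-RMS signal
    for (cp in coupling) {
      cp <- as.list(cp)
      noise_scale <- if (is.infinite(cp$snr)) 0 else 1 / cp$snr
      for (v in c(cp$i, cp$j)) data[, v, ] <- data[, v, ] * noise_scale
    }
    for (cp in coupling) {
      cp <- as.list(cp)
      for (tr in seq_len(n_trials)) {
        ph <- runif(1, 0, 2 * pi)
        sig_i <- sqrt(2) * cos(2 * pi * cp$freq_Hz * tt + ph)
        sig_j <- sqrt(2) * cos(2 * pi * cp$freq_Hz * tt + ph - cp$phase_lag_rad)
        data[tr, cp$i, ] <- data[tr, cp$i, ] + sig_i
        data[tr, cp$j, ] <- data[tr, cp$j, ] + sig_j
      }
    }
    coords <- matrix(rnorm(n_nodes * 3), n_nodes, 3) * 30
    node_timeseries(data, fs = fs, node_coords = coords, subject_id = "sim")
  })
}

#' Write a synthetic cohort to disk as plain-text tables
#'
#' Covariates as TSV (id, age_years, sex, handedness, mean_node_distance),
#' one N x N adjacency TSV per subject, and node coordinates as TSV
#' (node, x, y, z).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$covariates[, c("id", "age_years", "sex",
                                           "handedness", "mean_node_distance")],
                     file.path(dir, "covariates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (conn in cohort$connectomes) {
    write_connectome(conn, file.path(dir, paste0(conn$subject_id, ".tsv")))
    cc <- conn$node_coords
    utils::write.table(data.frame(node = seq_len(nrow(cc)), x = cc[, 1],
                                  y = cc[, 2], z = cc[, 3]),
                       file.path(dir, paste0(conn$subject_id, "_coords.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
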