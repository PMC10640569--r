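#' Induced subnetwork of a connectome
#'
#' Restricts a connectome to a node subset (e.g. a predefined language
#' network), recomputing the mean node distance on the subset.
#'
#' @param conn a [connectome()].
#' @param node_list integer indices of the nodes to keep.
#' @return a [connectome()] on the subset.
#' @export
subset_network <- function(conn, node_list) {
  stopifnot(inherits(conn, "connectome"))
  N <- nrow(conn$W)
  node_list <- as.integer(node_list)
  if (any(node_list < 1 | node_list > N) || anyDuplicated(node_list))
    stop("unknown or duplicated node id in subset")
  connectome(conn$W[node_list, node_list, drop = FALSE],
             node_coords = conn$node_coords[node_list, , drop = FALSE],
             subject_id = conn$subject_id,
             n_bins_aggregated = conn$n_bins_aggregated)
}

#' Sample age quartiles, ties to the lower quartile
#'
#' @param age numeric vector of ages.
#' @return integer vector in 1..4.
#' @export
age_quartiles <- function(age) {
  qs <- quantile(age, c(0.25, 0.5, 0.75))
  unname(1L + (age > qs[1]) + (age > qs[2]) + (age > qs[3]))
}

#' Pool quartile-level demographic summaries into an overall column
#'
#' Given per-quartile counts and means (columns `n`, `age_mean`, `male`,
#' `female`, `left`, `no_preference`, `right`), computes the pooled totals,
#' the n-weighted overall mean age and the overall percentage of females —
#' an internal-consistency check for quartile-wise demographic tables.
#'
#' @param tab data.frame with one row per quartile.
#' @return list: `n`, `mean_age`, `male`, `female`, `pct_female`, `left`,
#'   `no_preference`, `right`.
#' @export
pool_quartile_summaries <- function(tab) {
  n <- sum(tab$n)
  list(n = n,
       mean_age = sum(tab$n * tab$age_mean) / n,
       male = sum(tab$male),
       female = sum(tab$female),
       pct_female = 100 * sum(tab$female) / n,
       left = sum(tab$left),
       no_preference = sum(tab$no_preference),
       right = sum(tab$right))
}

#' Pipeline configuration
#'
#' @param mode input mode: "synthetic" (generate a cohort), "adjacency"
#'   (read weighted matrices + covariates from `input_dir`).
#' @param cohort a [cohort_spec()] for synthetic mode.
#' @param input_dir directory with `covariates.tsv` and one `<id>.tsv`
#'   adjacency per subject (adjacency mode).
#' @param strategies attack strategies to run.
#' @param densities density grid (default 1%..30% in 1% steps, a coarsened
#'   grid suitable for interactive work; the production default of the
#'   attack literature is 0.25%..100% in 0.25% steps).
#' @param n_iter attack iterations per density.
#' @param node_subset optional integer node indices for a sub-network
#'   analysis (run in addition to the full network).
#' @param map_density density at which removal-frequency maps are computed.
#' @param n_boot bootstrap replicates for confidence bands.
#' @param alpha significance level for the three-condition rule.
#' @param out_dir optional output directory; when set, all tables are
#'   written as TSV/JSON.
#' @param master_seed master seed for every random stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "adjacency"),
                            cohort = cohort_spec(),
                            input_dir = NULL,
                            strategies = c("random", "betweenness"),
                            densities = seq(0.01, 0.30, by = 0.01),
                            n_iter = 100L,
                            node_subset = NULL,
                            map_density = 0.05,
                            n_boot = 200L,
                            alpha = 0.001,
                            out_dir = NULL,
                            master_seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "adjacency") {
    if (is.null(input_dir) || !dir.exists(input_dir))
      stop_config("adjacency mode requires an existing input_dir")
  }
  structure(list(mode = mode, cohort = cohort, input_dir = input_dir,
                 strategies = strategies, densities = densities,
                 n_iter = as.integer(n_iter), node_subset = node_subset,
                 map_density = map_density, n_boot = as.integer(n_boot),
                 alpha = alpha, out_dir = out_dir,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Field names mirror [pipeline_config()]; the `cohort` block mirrors
#' [cohort_spec()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) y$cohort <- do.call(cohort_spec, y$cohort)
  if (!is.null(y$densities) && length(y$densities) == 3 &&
      !is.null(names(y$densities)))
    y$densities <- seq(y$densities[["from"]], y$densities[["to"]],
                       by = y$densities[["by"]])
  do.call(pipeline_config, y)
}

read_adjacency_cohort <- function(dir) {
  covs <- utils::read.table(file.path(dir, "covariates.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  conns <- lapply(covs$id, function(id) {
    coords_path <- file.path(dir, paste0(id, "_coords.tsv"))
    read_connectome(file.path(dir, paste0(id, ".tsv")),
                    coords_path = if (file.exists(coords_path)) coords_path)
  })
  if (!"mean_node_distance" %in% names(covs))
    covs$mean_node_distance <- vapply(conns, function(cn) cn$mean_distance,
                                      numeric(1))
  list(covariates = covs, connectomes = conns)
}

#' Run the full percolation / FDA / regression pipeline
#'
#' For each attack strategy (and each network: full, plus the optional node
#' subset): attacks across the density grid, terminal-spike and SSR outlier
#' removal, domain trimming, function-on-scalar regression of the
#' (unsmoothed) trimmed functions on age, sex, handedness and mean node
#' distance, bootstrap bands, the three-condition significance summary, and
#' removal-frequency maps for the first and fourth age quartiles. Age is
#' centered at the cohort mean before modeling.
#'
#' @param cfg a [pipeline_config()].
#' @return a report bundle (list, one entry per strategy x network) with a
#'   `manifest` recording seeds and per-stage subject counts; written to
#'   `cfg$out_dir` when set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  input <- if (cfg$mode == "synthetic") {
    spec <- cfg$cohort
    spec$master_seed <- cfg$master_seed
    generate_cohort(spec)
  } else {
    read_adjacency_cohort(cfg$input_dir)
  }
  covs <- input$covariates
  networks <- list(whole = input$connectomes)
  if (!is.null(cfg$node_subset))
    networks$subset <- lapply(input$connectomes, subset_network,
                              node_list = cfg$node_subset)

  bundle <- list()
  manifest <- list(master_seed = cfg$master_seed, n_input = nrow(covs),
                   stages = list())
  for (net in names(networks)) {
    conns <- networks[[net]]
    net_covs <- covs
    if (net == "subset")
      net_covs$mean_node_distance <- vapply(conns, function(cn) cn$mean_distance,
                                            numeric(1))
    for (strat in cfg$strategies) {
      key <- paste(net, strat, sep = ".")
      pfs <- lapply(seq_along(conns), function(i) {
        cfg_i <- attack_config(strategy = strat, densities = cfg$densities,
                               n_iter = cfg$n_iter,
                               seed = derive_seed(cfg$master_seed,
                                                  i + 7919L * match(strat,
                                                                    cfg$strategies)))
        run_attacks(conns[[i]], cfg_i)
      })
      fs <- functional_sample_from_attacks(pfs)
      fs <- drop_terminal_spike_outliers(fs)
      n_after_spike <- sum(fs$retained)
      fs <- trim_domain(fs, tol = 0.02, relative = TRUE)
      ssr <- drop_ssr_outliers(fs)
      fs <- ssr$fs
      n_after_ssr <- sum(fs$retained)

      keep <- fs$retained
      dat <- data.frame(
        age = net_covs$age_years[keep] - mean(net_covs$age_years[keep]),
        sex_female = as.numeric(net_covs$sex[keep] == "female"),
        hand_left = as.numeric(net_covs$handedness[keep] == "left"),
        hand_nopref = as.numeric(net_covs$handedness[keep] == "no_preference"),
        mean_distance = net_covs$mean_node_distance[keep])
      # drop constant indicator columns (e.g. no left-handers in sample)
      dat <- dat[, vapply(dat, function(v) length(unique(v)) > 1, logical(1)),
                 drop = FALSE]
      fml <- stats::as.formula(paste("fs ~", paste(names(dat), collapse = " + ")))
      fit <- fosr(fml, data = dat)
      ci <- confint(fit, n_boot = cfg$n_boot,
                    seed = derive_seed(cfg$master_seed, 104729L))
      sig <- significance_summary(fit, ci, alpha = cfg$alpha)

      quart <- age_quartiles(net_covs$age_years)
      map_d <- cfg$densities[which.min(abs(cfg$densities - cfg$map_density))]
      maps <- list(
        q1 = removal_frequency_map(pfs, map_d,
                                   subjects = net_covs$id[quart == 1]),
        q4 = removal_frequency_map(pfs, map_d,
                                   subjects = net_covs$id[quart == 4]))

      manifest$stages[[key]] <- list(
        n_input = nrow(covs),
        dropped_terminal_spike = nrow(covs) - n_after_spike,
        dropped_ssr = n_after_spike - n_after_ssr,
        n_retained = n_after_ssr,
        trimmed_grid = range(fs$densities[fs$trim]),
        map_density = map_d)
      bundle[[key]] <- list(percolation = percolation_table(pfs),
                            sample = fs, fit = fit, ci = ci,
                            significance = sig, maps = maps,
                            smooth_table = ssr$table)
    }
  }
  bundle$covariates <- covs
  bundle$manifest <- manifest

  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg)
  invisible(bundle)
}

write_bundle <- function(bundle, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(x, file.path(cfg$out_dir, f),
                                           sep = "\t", row.names = FALSE,
                                           quote = FALSE)
  for (key in setdiff(names(bundle), c("manifest", "covariates"))) {
    r <- bundle[[key]]
    tsv(r$percolation, paste0(key, "_percolation.tsv"))
    tsv(coef(r$fit), paste0(key, "_beta.tsv"))
    tsv(r$significance, paste0(key, "_significance.tsv"))
    tsv(r$maps$q1, paste0(key, "_map_q1.tsv"))
    tsv(r$maps$q4, paste0(key, "_map_q4.tsv"))
    tsv(r$smooth_table, paste0(key, "_smoothing.tsv"))
    s <- r$fit
    jsonlite::write_json(
      list(F = unname(s$overall[["F"]]), p = unname(s$overall[["p"]]),
           r_squared = s$r_squared,
           functional_r2 = s$functional_r2,
           semipartial = as.list(s$semipartial)),
      file.path(cfg$out_dir, paste0(key, "_model.json")),
      auto_unbox = TRUE, digits = NA)
  }
  tsv(bundle$covariates, "covariates.tsv")
  jsonlite::write_json(bundle$manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
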