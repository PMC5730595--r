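#' Default run configuration
#'
#' A plain-text (YAML) key-value configuration driving [run_pipeline()].
#' Every stochastic stage derives its seed from `master_seed` by
#' counter-based splitting, so stages are reproducible and
#' order-independent. The configuration round-trips losslessly through
#' [write_run_config()] / [read_run_config()].
#'
#' @return A `run_config` list.
#' @export
default_run_config <- function() {
  structure(
    list(
      master_seed = 1L,
      # paths$input may be set to analyse an existing measurement CSV
      paths = list(out_dir = "results"),
      params = list(v0 = 2.25, d0 = 1.125, v1 = 45, d1 = 0.09),
      extrinsic = list(mean_v1 = 45, var_v1 = 100),
      spatial = list(k_neighbours = 39, n_tiers = 5, n_permutations = 5000),
      # mean_division_time may be added; absent means the calibrated default
      inheritance = list(n_pairs = 2000),
      tissue = list(n_cells = 500, coupling = 0.5, correlation_length_um = 15),
      kik = list(n_cells = 400, measurement_noise_sd = 0.1),
      ks_alpha = 0.05
    ),
    class = "run_config"
  )
}

#' Read / write a run configuration
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a `run_config` list; missing keys are
#'   filled from [default_run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "noisetissue_schema_error")
  }
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_run_config()), user)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

run_config_objects <- function(config) {
  list(
    params = two_stage_params(
      config$params$v0, config$params$d0,
      config$params$v1, config$params$d1
    ),
    spec = extrinsic_spec(config$extrinsic$mean_v1, config$extrinsic$var_v1)
  )
}

#' Run one pipeline stage
#'
#' Executes the named analysis stage, writing its CSV outputs and a YAML
#' log (seeds, parameters, exclusion counts) to `out_dir`. Stages:
#' \describe{
#'   \item{synth}{generate a synthetic tissue + ground truth}
#'   \item{simulate}{photoconversion trajectory cohort}
#'   \item{kik-decay}{synthetic pulse-chase + decay-rate estimate}
#'   \item{temporal}{3 h / 6 h correlation of the green reporter}
#'   \item{noise}{per-image dual-reporter noise decomposition}
#'   \item{spatial}{neighbour coupling + randomization test}
#'   \item{tiers}{distance-tier coupling profile}
#'   \item{inherit}{division inheritance simulation (both modes)}
#' }
#' Stages that need a nucleus table read `paths$input` if set, otherwise
#' generate a synthetic one. Input files are never modified.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param stage Stage identifier.
#' @param out_dir Output directory (created if needed); overrides
#'   `config$paths$out_dir`.
#' @param seed Optional master-seed override.
#' @return Named list of the result tibbles, invisibly; files are written
#'   to `out_dir`.
#' @export
run_pipeline <- function(config = default_run_config(), stage,
                         out_dir = NULL, seed = NULL) {
  stages <- c(
    "synth", "simulate", "kik-decay", "temporal", "noise", "spatial",
    "tiers", "inherit"
  )
  if (!stage %in% stages) {
    abort(
      paste0("unknown stage '", stage, "'; use one of: ", paste(stages, collapse = ", ")),
      class = "noisetissue_usage_error"
    )
  }
  if (!is.null(seed)) config$master_seed <- as.integer(seed)
  out_dir <- out_dir %||% config$paths$out_dir %||% "results"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ob <- run_config_objects(config)
  ms <- config$master_seed
  log <- list(stage = stage, master_seed = ms, timestamp = format(Sys.time()))
  results <- list()

  tissue_input <- function(seed_counter) {
    if (!is.null(config$paths$input)) {
      read_nucleus_table(config$paths$input)
    } else {
      tcfg <- do.call(tissue_gen_config, utils::modifyList(
        config$tissue,
        list(seed = derive_seed(ms, seed_counter))
      ))
      generate_tissue(tcfg)$table
    }
  }

  if (stage == "synth") {
    tcfg <- do.call(tissue_gen_config, utils::modifyList(
      config$tissue, list(seed = derive_seed(ms, 10))
    ))
    gen <- generate_tissue(tcfg)
    write_nucleus_table(gen$table, file.path(out_dir, "synthetic_table.csv"))
    readr::write_csv(gen$truth, file.path(out_dir, "ground_truth.csv"))
    results <- gen
  } else if (stage == "simulate") {
    tr <- simulate_trajectories(ob$params, ob$spec,
      n_cells = 20, t_end = 6,
      seed = derive_seed(ms, 20)
    )
    write_trajectories(tr, file.path(out_dir, "trajectories.csv"))
    results$trajectories <- tr
  } else if (stage == "kik-decay") {
    gen <- generate_kik_timecourse(ob$params, ob$spec,
      n_cells = config$kik$n_cells,
      measurement_noise_sd = config$kik$measurement_noise_sd,
      seed = derive_seed(ms, 30)
    )
    avg <- average_duplicates(gen$table)
    red <- tibble::as_tibble(avg) |>
      dplyr::filter(.data$channel == "KikR", .data$time_h %in% c(3, 6)) |>
      dplyr::mutate(net = .data$mean_grey - .data$background_mean_grey) |>
      dplyr::select("cell_id", "time_h", "net") |>
      tidyr::pivot_wider(names_from = "time_h", values_from = "net")
    est <- estimate_decay_rate(red$`3`, red$`6`, dt = 3)
    readr::write_csv(est, file.path(out_dir, "decay_rate.csv"))
    log$n_excluded <- est$n_excluded
    results$decay <- est
  } else if (stage == "temporal") {
    gen <- generate_kik_timecourse(ob$params, ob$spec,
      n_cells = config$kik$n_cells,
      measurement_noise_sd = config$kik$measurement_noise_sd,
      seed = derive_seed(ms, 40)
    )
    norm <- normalize_table(average_duplicates(gen$table))
    out <- purrr::map_dfr(c("pearson", "spearman"), function(mth) {
      dplyr::mutate(
        kik_temporal_correlation(norm, method = mth),
        method = mth
      )
    })
    readr::write_csv(out, file.path(out_dir, "temporal_correlation.csv"))
    results$temporal <- out
  } else if (stage == "noise") {
    tab <- tissue_input(50)
    norm <- normalize_table(average_duplicates(tab))
    per_image <- aggregate_noise(norm, ks_alpha = config$ks_alpha)
    groups <- summarise_noise_groups(per_image)
    readr::write_csv(per_image, file.path(out_dir, "noise_per_image.csv"))
    readr::write_csv(groups, file.path(out_dir, "noise_groups.csv"))
    results <- list(per_image = per_image, groups = groups)
  } else if (stage %in% c("spatial", "tiers")) {
    tab <- tissue_input(60)
    norm <- normalize_table(average_duplicates(tab))
    scfg <- spatial_config(
      k_neighbours = config$spatial$k_neighbours,
      n_tiers = config$spatial$n_tiers,
      n_permutations = config$spatial$n_permutations,
      seed = derive_seed(ms, 61)
    )
    sc <- spatial_coupling(norm, scfg)
    spat <- glance(sc)
    tiers <- tidy(sc)
    readr::write_csv(spat, file.path(out_dir, "spatial_coupling.csv"))
    readr::write_csv(tiers, file.path(out_dir, "tier_profile.csv"))
    results <- list(spatial = spat, tiers = tiers)
  } else if (stage == "inherit") {
    out <- purrr::map_dfr(c("state_only", "full"), function(md) {
      icfg <- inheritance_config(ob$params, ob$spec,
        mode = md,
        mean_division_time = config$inheritance$mean_division_time,
        n_pairs = config$inheritance$n_pairs,
        seed = derive_seed(ms, 70 + (md == "full"))
      )
      ens <- simulate_division_pairs(icfg)
      dplyr::mutate(sibling_correlation(ens), seed = icfg$seed)
    })
    readr::write_csv(out, file.path(out_dir, "inheritance.csv"))
    results$inheritance <- out
  }

  yaml::write_yaml(log, file.path(out_dir, paste0("run_log_", gsub("-", "_", stage), ".yaml")))
  invisible(results)
}
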