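#' Built-in simulation scenarios
#'
#' Named scenarios bundling a [sim_config()] with matched analysis
#' parameters. `"dispersed-DM"` is a fully dispersed defined-medium
#' fermentation (exponential growth until substrate exhaustion);
#' `"pelleted-DM"` adds a pellet-formation transition to linear growth at
#' 40 h; `"vulpinum-like"` reproduces the narrative of a pelleted
#' defined-medium run that grows exponentially until 36 h and reaches its
#' CO2 maximum just after 110 h (a 74 h non-exponential phase);
#' `"feature-demo"` is an LC-MS feature-table scenario with five planted
#' known compounds.
#'
#' Lag-detection thresholds are scenario-specific because a meaningful
#' threshold must be commensurate with the scale of the simulated exhaust
#' CO2 (fractions of a percent at these airflows and substrate levels).
#'
#' @param name Scenario name.
#' @param seed Root seed stored in the configuration.
#' @return List with `config` (a `sim_config`, physiology scenarios),
#'   `params` (analysis parameters) and for `"feature-demo"` a `library` and
#'   `planted` table.
#' @export
scenario_config <- function(name = c("dispersed-DM", "pelleted-DM",
                                     "vulpinum-like", "feature-demo"),
                            seed = 1L) {
  known <- c("dispersed-DM", "pelleted-DM", "vulpinum-like", "feature-demo")
  if (!is.character(name) || !(name[1] %in% known)) {
    abort(paste0("unknown scenario '", name[1], "'; available: ",
                 paste(known, collapse = ", ")),
          class = "fermkin_config_error")
  }
  name <- name[1]
  params <- list(k_consecutive = 3, r2_min = 0.99, min_points = 3,
                 smooth_window_h = 1, mu_r2_min = 0.96, min_dw_gl = 0.2,
                 inlet_co2_pct = 0.04)
  switch(name,
    "dispersed-DM" = {
      params$threshold_pct <- 0.1
      list(name = name,
           config = sim_config(mu_max = 0.2, lag_h = 14, x0 = 0.003,
                               y_cx = 1.0, m_co2 = 0.02, seed = seed),
           params = params)
    },
    "pelleted-DM" = {
      params$threshold_pct <- 0.25
      x_p <- 0.01 * exp(0.2 * (40 - 12))
      x_max <- 0.01 + 0.5 * 15
      list(name = name,
           config = sim_config(mu_max = 0.2, lag_h = 12, x0 = 0.01,
                               y_cx = 0.5, m_co2 = 0.06, t_pellet_h = 40,
                               nonexp_rate = (x_max - x_p) / 50,
                               offgas_interval_min = 30, replicate_cv = 0,
                               seed = seed),
           params = params)
    },
    "vulpinum-like" = {
      params$threshold_pct <- 0.2
      x_p <- 0.01 * exp(0.22 * (36 - 12))
      x_max <- 0.01 + 0.5 * 15
      list(name = name,
           config = sim_config(mu_max = 0.22, lag_h = 12, x0 = 0.01,
                               y_cx = 0.5, m_co2 = 0.04, t_pellet_h = 36,
                               nonexp_rate = (x_max - x_p) / 74.3,
                               offgas_interval_min = 30, t_end_h = 130,
                               replicate_cv = 0, seed = seed),
           params = params)
    },
    "feature-demo" = {
      library <- compound_library(tibble(
        name = c("griseofulvin", "dechlorogriseofulvin", "roquefortine C",
                 "penicillic acid", "andrastin A", "chanoclavine"),
        formula = c("C17H17ClO6", "C17H18O6", "C22H23N5O2",
                    "C8H10O4", "C28H38O7", "C16H20N2O"),
        rt_min = c(6.8, 6.2, 4.9, 2.7, 9.1, 1.8)))
      planted <- tibble(
        name = c("griseofulvin", "dechlorogriseofulvin", "roquefortine C",
                 "penicillic acid", "andrastin A"),
        area = c(2e6, 8e5, 4e6, 1.2e6, 6e5),
        intensity = c(5e4, 2e4, 9e4, 3e4, 1.5e4))
      list(name = name, library = library, planted = planted,
           params = list(min_area = 5e5, min_intensity = 1e4,
                         mz_tol_ppm = 10, rt_tol_min = 0.1, seed = seed))
    })
}

#' Physiology pipeline over replicate runs
#'
#' Runs gas balance, phase segmentation and kinetics over a set of replicate
#' fermentations and aggregates the result. A failure in one run is logged
#' as a warning and reported; remaining runs are still processed.
#'
#' @param runs List of `fermentation_run` objects (e.g. from
#'   [simulate_triplicate()]), or a scenario name understood by
#'   [scenario_config()].
#' @param params Analysis parameters (as in `scenario_config()$params`);
#'   when `runs` is a scenario name its own parameters are used.
#' @param seed Seed, used only when `runs` is a scenario name.
#' @param out_dir Optional directory to write `segmentation.csv`,
#'   `kinetics.csv` and `summary.csv` into.
#' @return List: `segmentation` (one row per run), `kinetics` (one row per
#'   run), `summary` (per-parameter replicate summary), `failures` (run ids
#'   with stage and message).
#' @export
run_physiology <- function(runs, params = NULL, seed = 1L, out_dir = NULL) {
  if (is.character(runs)) {
    sc <- scenario_config(runs, seed = seed)
    params <- params %||% sc$params
    runs <- simulate_triplicate(sc$config)
  }
  params <- params %||% scenario_config("dispersed-DM")$params

  seg_rows <- list(); kin_rows <- list(); fails <- list()
  for (i in seq_along(runs)) {
    id <- names(runs)[i] %||% paste0("run", i)
    if (id == "") id <- paste0("run", i)
    res <- tryCatch({
      seg <- segment_run(runs[[i]],
                         threshold_pct = params$threshold_pct,
                         k_consecutive = params$k_consecutive,
                         r2_min = params$r2_min,
                         min_points = params$min_points,
                         smooth_window_h = params$smooth_window_h,
                         inlet_co2_pct = params$inlet_co2_pct)
      kin <- analyze_run(runs[[i]], seg, mu_r2_min = params$mu_r2_min,
                         min_dw_gl = params$min_dw_gl)
      list(seg = dplyr::bind_cols(tibble(run_id = id), tidy(seg)),
           kin = dplyr::bind_cols(tibble(run_id = id), kin))
    }, fermkin_segmentation_error = function(e) {
      warn(sprintf("run '%s' failed at stage '%s': %s", id,
                   e$stage %||% "?", conditionMessage(e)))
      tibble(run_id = id, stage = e$stage %||% NA_character_,
             message = conditionMessage(e))
    })
    if (is.data.frame(res)) {
      fails[[id]] <- res
    } else {
      seg_rows[[id]] <- res$seg
      kin_rows[[id]] <- res$kin
    }
  }
  kinetics <- bind_rows(kin_rows)
  out <- list(
    segmentation = bind_rows(seg_rows),
    kinetics = kinetics,
    summary = if (nrow(kinetics)) summarize_triplicate(kinetics) else tibble(),
    failures = bind_rows(fails)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(out$segmentation, file.path(out_dir, "segmentation.csv"))
    readr::write_csv(out$kinetics, file.path(out_dir, "kinetics.csv"))
    readr::write_csv(out$summary, file.path(out_dir, "summary.csv"))
  }
  out
}

#' Metabolite pipeline over replicate feature tables
#'
#' Thresholds the replicate tables of the latest-time sample into a pooled,
#' deduplicated candidate list, counts candidates reproducibly present in at
#' least two replicates, and (when a library is supplied) dereplicates the
#' candidates by accurate mass.
#'
#' @param tables List of replicate feature tibbles (one sampling time).
#' @param library Optional [compound_library()].
#' @param min_area,min_intensity Candidate thresholds.
#' @param mz_tol_ppm,rt_tol_min Matching tolerances.
#' @param out_dir Optional output directory for `candidates.csv` and
#'   `dereplication.csv`.
#' @return List: `candidates`, `n_candidates`, `n_reproducible`,
#'   `dereplication` (empty tibble without a library).
#' @export
run_metabolites <- function(tables, library = NULL, min_area = 5e5,
                            min_intensity = 1e4, mz_tol_ppm = 10,
                            rt_tol_min = 0.1, out_dir = NULL) {
  cand <- bind_rows(lapply(tables, threshold_features,
                           min_area = min_area, min_intensity = min_intensity))
  cand <- dedupe_candidates(cand, mz_tol_ppm, rt_tol_min)
  n_rep <- count_reproducible(tables, cand, mz_tol_ppm, rt_tol_min)
  der <- if (!is.null(library) && nrow(cand)) {
    dereplicate(cand, library, mz_tol_ppm = mz_tol_ppm,
                rt_tol_min = rt_tol_min)
  } else {
    tibble(feature_id = character(), compound = character(),
           ppm_error = numeric())
  }
  out <- list(candidates = cand, n_candidates = nrow(cand),
              n_reproducible = n_rep, dereplication = der)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(cand, file.path(out_dir, "candidates.csv"))
    readr::write_csv(der, file.path(out_dir, "dereplication.csv"))
  }
  out
}

#' Write a simulated scenario to disk as CSV fixtures
#'
#' Deterministically materializes a scenario: per-replicate off-gas,
#' dry-weight and glucose CSVs plus a ground-truth ledger (physiology
#' scenarios), or per-replicate feature tables, the compound library and the
#' planted-truth ledger (`"feature-demo"`).
#'
#' @param scenario Scenario name, see [scenario_config()].
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; identical seeds give identical file trees.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(scenario, dir, seed = 1L) {
  sc <- scenario_config(scenario, seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(x, f) {
    p <- file.path(dir, f)
    readr::write_csv(x, p)
    p
  }
  if (scenario == "feature-demo") {
    ft <- simulate_feature_tables(sc$planted, sc$library, n_noise = 20,
                                  dropout = 0.1, seed = seed)
    for (i in seq_along(ft$tables)) {
      paths <- c(paths, wr(ft$tables[[i]], sprintf("features_rep%d.csv", i)))
    }
    paths <- c(paths,
               wr(as_tibble(sc$library), "library.csv"),
               wr(ft$truth, "ground_truth.csv"))
  } else {
    runs <- simulate_triplicate(sc$config)
    for (i in seq_along(runs)) {
      paths <- c(paths,
                 wr(runs[[i]]$off_gas, sprintf("offgas_rep%d.csv", i)),
                 wr(runs[[i]]$dry_weight, sprintf("dryweight_rep%d.csv", i)),
                 wr(runs[[i]]$glucose, sprintf("glucose_rep%d.csv", i)))
    }
    paths <- c(paths, wr(bind_rows(lapply(runs, ground_truth)),
                         "ground_truth.csv"))
  }
  invisible(paths)
}
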