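## End-to-end orchestration: simulate a campaign, synthesize per-dataset
## anomalous difference maps, find and match peaks, classify sites by edge
## contrast, estimate occupancies for iodine calls, optionally select a
## conformer ensemble, and write a JSON + text report.  Everything is a
## pure function of (config, master seed).

#' Campaign configuration
#'
#' Validates and normalizes the configuration of a full pipeline run.
#'
#' @param preset Crystal preset (`"L19"`, `"K20"`, `"L18"`) or NULL when
#'   `model_path` is given.
#' @param model_path Optional PDB path of a ground-truth model.
#' @param plan data.frame of plan rows (`energy`, `orientation`, `crystal`,
#'   `dose_inc`); default is the paper-like two-orientation above-edge plus
#'   one below-edge schedule on a single crystal.
#' @param target_f_over_sig,completeness Noise settings (see [noise_spec()]).
#' @param strong_sigma,absent_sigma,match_tol,min_support Validation
#'   thresholds (see [classify_sites()] and [match_peaks()]).
#' @param d_min Resolution limit in Angstrom.
#' @param d_half Probe half-dose in MGy.
#' @param refine_starts Multi-start count for occupancy estimation (0
#'   disables the stage).
#' @param refine_cycles Gauss-Newton cycles per start.
#' @param select_pool Optional [conformer_pool()] (or multi-model PDB path)
#'   enabling the ensemble-selection stage.
#' @param select_n Ensemble size for selection.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param outdir Output directory (NULL = no files written).
#' @return Object of class `campaign_config`.
#' @export
campaign_config <- function(preset = "L19", model_path = NULL, plan = NULL,
                            target_f_over_sig = 15, completeness = 1,
                            strong_sigma = 6, absent_sigma = 4,
                            match_tol = 1.5, min_support = 2,
                            d_min = 2.0, d_half = 6,
                            refine_starts = 500, refine_cycles = 50,
                            select_pool = NULL, select_n = 3,
                            seed = 1, outdir = NULL) {
  if (is.null(plan))
    plan <- data.frame(
      energy = c(5.2, 5.2, 4.5),
      orientation = c("kappa=0", "kappa=-20", "kappa=0"),
      crystal = "xtal1",
      dose_inc = c(1.35, 1.4, 8.32))
  stopifnot(is.data.frame(plan),
            all(c("energy", "orientation", "crystal", "dose_inc") %in% names(plan)),
            nrow(plan) >= 1, all(plan$dose_inc >= 0),
            strong_sigma > 0, absent_sigma > 0, match_tol > 0,
            min_support >= 1, d_min > 0, d_half > 0, refine_starts >= 0)
  structure(list(preset = preset, model_path = model_path, plan = plan,
                 target_f_over_sig = target_f_over_sig,
                 completeness = completeness, strong_sigma = strong_sigma,
                 absent_sigma = absent_sigma, match_tol = match_tol,
                 min_support = min_support, d_min = d_min, d_half = d_half,
                 refine_starts = refine_starts, refine_cycles = refine_cycles,
                 select_pool = select_pool, select_n = select_n,
                 seed = as.integer(seed), outdir = outdir),
            class = "campaign_config")
}

#' Read a campaign configuration from YAML
#'
#' Scalar fields map directly onto [campaign_config()] arguments; `plan`
#' is a list of row-maps.
#'
#' @param path YAML file path.
#' @return A [campaign_config()].
#' @export
read_campaign_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$plan))
    y$plan <- do.call(rbind, lapply(y$plan, as.data.frame))
  do.call(campaign_config, y)
}

.dataset_ref <- function(ds)
  sprintf("E%.2f_%s_%s", ds$energy, ds$orientation_label, ds$crystal_id)

#' Run the full detection pipeline
#'
#' Chains simulation, anomalous difference map synthesis, sigma peak
#' search, cross-dataset consensus, edge-contrast classification,
#' dose-decay checks and (optionally) occupancy estimation and ensemble
#' selection.  The run is deterministic given the configuration, and
#' INFO-level messages narrate the per-site decision chain.
#'
#' @param config A [campaign_config()].
#' @param verbose Emit progress messages (default TRUE).
#' @return List of class `pipeline_report`: `datasets` (labels, doses),
#'   `peaks` (per-dataset), `sites` (classified site table),
#'   `decay` (per-site dose-decay ratios), `occupancy` (list of
#'   [multistart_refine()] summaries for iodine calls), `selection`
#'   (optional [select_ensemble()] result), `config` (resolved
#'   configuration).  If `config$outdir` is set, a JSON and a text report
#'   plus per-dataset peak lists are written there.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "campaign_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  model <- stage("model", {
    if (!is.null(config$model_path)) read_pdb_model(config$model_path)
    else build_paper_like_crystal(config$preset,
                                  seed = derive_seed(config$seed, "crystal"))
  })
  say("model: %d sites, %d probes", nrow(model$sites),
      sum(model$sites$role == "probe"))

  noise <- noise_spec(config$target_f_over_sig, config$completeness,
                      derive_seed(config$seed, "noise"))
  datasets <- stage("simulate",
                    simulate_campaign(model, config$plan, noise,
                                      config$d_half, config$d_min))

  e_hi <- edge_energy("I", "L_I"); e_lo <- edge_energy("I", "L_III")
  refs <- vapply(datasets, .dataset_ref, "")
  above <- refs[vapply(datasets, function(d) d$energy > e_hi, logical(1))]
  below <- refs[vapply(datasets, function(d) d$energy < e_lo, logical(1))]

  peak_lists <- stage("maps+peaks", {
    out <- list()
    for (i in seq_along(datasets)) {
      ds <- datasets[[i]]
      ph <- model_phases(model, ds$refl)
      mp <- anomalous_difference_map(ds$refl, ph)
      pk <- find_peaks(mp, threshold_sigma = config$absent_sigma)
      say("dataset %s: %d peaks >= %.1f sigma (map rms %.3g)",
          refs[i], nrow(pk), config$absent_sigma, mp$rms)
      out[[refs[i]]] <- pk
    }
    out
  })

  sites <- stage("classify", {
    clusters <- match_peaks(peak_lists, config$match_tol, model$cell, model$symops)
    classify_sites(clusters, above, below, config$strong_sigma,
                   config$absent_sigma, config$min_support,
                   cell = model$cell, symops = model$symops)
  })
  if (!is.null(sites)) for (i in seq_len(nrow(sites)))
    say("site %d: %s (above %.1f sigma in %d datasets, below max %.1f)",
        i, sites$classification[i], sites$max_above[i],
        sites$n_above_support[i], sites$max_below[i])

  # dose-decay ratios across same-energy datasets of one crystal
  decay <- NULL
  hi_sets <- refs[vapply(datasets, function(d) d$energy > e_hi, logical(1))]
  if (length(hi_sets) >= 2 && !is.null(sites) && nrow(sites)) {
    decay <- lapply(seq_len(nrow(sites)), function(i) {
      hts <- as.numeric(sites[i, paste0("h_", hi_sets)])
      dose_decay_check(hts)
    })
  }

  occ <- list()
  if (config$refine_starts > 0 && !is.null(sites)) {
    iod <- which(sites$classification == "iodine")
    first_above <- datasets[[match(above[1], refs)]]
    for (i in iod) {
      pos <- unlist(sites[i, c("x", "y", "z")])
      dists <- vapply(seq_len(nrow(model$sites)), function(j)
        min_sym_distance(model$cell, model$symops, pos,
                         unlist(model$sites[j, c("x", "y", "z")])), numeric(1))
      j <- which.min(dists)
      if (dists[j] > config$match_tol || model$sites$role[j] != "probe") next
      lab <- model$sites$label[j]
      est <- stage("refine-occ",
                   multistart_refine(first_above$refl, model, lab,
                                     first_above$energy,
                                     n_starts = config$refine_starts,
                                     n_cycles = config$refine_cycles,
                                     seed = derive_seed(config$seed, "occref", lab)))
      say("occupancy %s: mode (%.2f, %.0f A^2)", lab, est$occ_mode, est$b_mode)
      occ[[lab]] <- est
    }
  }

  selection <- NULL
  if (!is.null(config$select_pool) && !is.null(sites)) {
    iod <- sites[sites$classification == "iodine", , drop = FALSE]
    if (nrow(iod)) {
      pool <- if (is.character(config$select_pool))
        read_pool_pdb(config$select_pool, model$cell, model$symops)
      else config$select_pool
      labs <- names(pool$conformers[[1]]$probe_positions)
      obs <- observed_sites(rep_len(labs, nrow(iod)), iod$x, iod$y, iod$z,
                            iod$max_above)
      selection <- stage("select",
                         select_ensemble(pool, obs, config$select_n, "exchange"))
      say("selection: fit error %.3f A over %d sites", selection$fit_error, nrow(obs))
    }
  }

  report <- structure(list(
    datasets = data.frame(ref = refs,
                          energy = vapply(datasets, `[[`, 0, "energy"),
                          dose_before = vapply(datasets, `[[`, 0, "dose_before"),
                          dose_after = vapply(datasets, `[[`, 0, "dose_after")),
    peaks = peak_lists, sites = sites, decay = decay,
    occupancy = lapply(occ, function(e)
      e[c("site_label", "occ_mode", "b_mode", "occ_mean", "b_mean")]),
    selection = selection,
    config = config[setdiff(names(config), "select_pool")]),
    class = "pipeline_report")

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(.report_json(report),
                         file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(sites))
      write_site_report(sites, model$cell, file.path(config$outdir, "sites"))
    for (nm in names(peak_lists))
      write_peaks(peak_lists[[nm]], file.path(config$outdir, paste0("peaks_", nm, ".tsv")), nm)
  }
  report
}

.report_json <- function(report) {
  list(datasets = report$datasets,
       sites = report$sites,
       n_iodine = if (is.null(report$sites)) 0
                  else sum(report$sites$classification == "iodine"),
       decay = report$decay,
       occupancy = report$occupancy,
       selection = if (is.null(report$selection)) NULL else
         report$selection[c("member_ids", "fit_error", "per_site_error")],
       config = report$config[c("preset", "target_f_over_sig", "strong_sigma",
                                "absent_sigma", "match_tol", "min_support",
                                "d_min", "d_half", "seed")])
}

#' @export
print.pipeline_report <- function(x, ...) {
  n_iod <- if (is.null(x$sites)) 0 else sum(x$sites$classification == "iodine")
  cat(sprintf("pipeline report: %d datasets, %d consensus sites, %d iodine calls\n",
              nrow(x$datasets), if (is.null(x$sites)) 0 else nrow(x$sites), n_iod))
  invisible(x)
}
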