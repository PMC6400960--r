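#' Assemble a full run configuration
#'
#' One plain list (YAML-serializable, bit-exact round trip) holding every
#' knob of a simulate / reconstruct / train / predict / evaluate run. A
#' content hash over the semantic fields stamps every artifact so results can
#' be traced to the exact configuration that produced them.
#'
#' @param n_train,n_val,n_test dataset sizes.
#' @param level photon level tag passed to [make_dataset()].
#' @param seed global seed; fans out via [seed_streams()].
#' @param axis_gates,axis_width temporal axis parameters.
#' @param bank_order,bank_k,bank_ranking pattern bank parameters.
#' @param irf_fwhm,irf_t0 Gaussian IRF parameters (ns).
#' @param tv named list overriding [tv_config()] fields.
#' @param fit named list overriding [fit_config()] fields.
#' @param net named list overriding [net_config()] fields.
#' @param gate_bin gate binning factor for the TV route.
#' @return object of class `run_config`.
#' @export
run_config <- function(n_train = 2000L, n_val = 500L, n_test = 40L,
                       level = "full", seed = 1L,
                       axis_gates = 256L, axis_width = 0.040,
                       bank_order = 1024L, bank_k = 512L,
                       bank_ranking = "sequency",
                       irf_fwhm = 0.2, irf_t0 = 1.0,
                       tv = list(), fit = list(), net = list(),
                       gate_bin = 4L) {
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test), level = level,
                 seed = as.integer(seed),
                 axis_gates = as.integer(axis_gates), axis_width = axis_width,
                 bank_order = as.integer(bank_order),
                 bank_k = as.integer(bank_k), bank_ranking = bank_ranking,
                 irf_fwhm = irf_fwhm, irf_t0 = irf_t0,
                 tv = tv, fit = fit, net = net,
                 gate_bin = as.integer(gate_bin)),
            class = "run_config")
}

#' Content hash of a run configuration
#'
#' MD5 over the canonical serialization of the semantic fields; changes iff
#' any semantic field changes.
#'
#' @param cfg a [run_config()].
#' @return character MD5 hash.
#' @export
config_hash <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(cfg), tf, version = 3, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return `read_run_config`: a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param cfg a [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

pipeline_objects <- function(cfg) {
  axis <- temporal_axis(cfg$axis_gates, cfg$axis_width)
  bank <- build_hadamard_bank(cfg$bank_order, cfg$bank_k, cfg$bank_ranking)
  irf <- gaussian_irf(axis, cfg$irf_fwhm, cfg$irf_t0)
  tvc <- do.call(tv_config, cfg$tv)
  fitc <- do.call(fit_config, cfg$fit)
  netc <- do.call(net_config, c(list(n_gates = cfg$axis_gates,
                                     n_meas = cfg$bank_k), cfg$net))
  list(axis = axis, bank = bank, irf = irf, tvc = tvc, fitc = fitc,
       netc = netc)
}

#' Run the simulate / reconstruct / train / predict / evaluate pipeline
#'
#' Executes the requested stages in order, writing every artifact under
#' `out_dir` stamped with the configuration hash. Stage dependencies are
#' checked: a stage whose upstream artifact is missing fails with an error
#' naming that stage. Reruns with the same configuration and seed reproduce
#' identical artifacts.
#'
#' Artifacts: `test.dataset` (scenes + measurements), `tvrecon.rds`
#' (TV reconstructions), `model.rds` (trained network), `netflics.rds`
#' (network reconstructions), `report_tvrecon.csv/json` and
#' `report_netflics.csv/json`.
#'
#' @param cfg a [run_config()].
#' @param stages character subset of
#'   `c("simulate", "tvrecon", "train", "predict", "evaluate")`.
#' @param out_dir output directory (created if missing).
#' @param verbose log stage progress and timings to stderr.
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "tvrecon", "evaluate"),
                         out_dir = "flics_run", verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  known <- c("simulate", "tvrecon", "train", "predict", "evaluate")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage name(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  seeds <- seed_streams(cfg$seed)
  ob <- pipeline_objects(cfg)
  paths <- list(dataset = file.path(out_dir, "test.dataset"),
                tvrecon = file.path(out_dir, "tvrecon.rds"),
                model = file.path(out_dir, "model.rds"),
                netflics = file.path(out_dir, "netflics.rds"))
  log <- function(...) if (verbose) message(sprintf(...))
  need <- function(path, stage, wanted)
    if (!file.exists(path))
      stop("stage '", stage, "' needs the artifact of stage '", wanted,
           "' (", path, " is missing)")
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- force(expr)
    log("[%s] done in %.1f s (config %s, seed %d)", name,
        proc.time()[["elapsed"]] - t0, substr(hash, 1, 8), cfg$seed)
    r
  }

  if ("simulate" %in% stages) t_stage("simulate", {
    scenes <- make_dataset(cfg$n_test, "test", level = cfg$level,
                           rng_seed = seeds[["phantoms"]])
    noise_seeds <- with_seed(seeds[["noise"]],
                             sample.int(.Machine$integer.max - 1L,
                                        length(scenes)))
    meas <- lapply(seq_along(scenes), function(i)
      simulate_sample(scenes[[i]], ob$bank, ob$irf, ob$axis,
                      rng_seed = noise_seeds[i])$measurements)
    names(meas) <- vapply(scenes, function(s) s$scene_id, character(1))
    write_dataset(paths$dataset, scenes, meas,
                  meta = list(config_hash = hash, seed = cfg$seed),
                  overwrite = TRUE)
  })

  if ("tvrecon" %in% stages) t_stage("tvrecon", {
    need(paths$dataset, "tvrecon", "simulate")
    ds <- read_dataset(paths$dataset)
    recons <- lapply(ds$scene_ids, function(id) {
      r <- reconstruct_tv(ds$measurements[[id]], ob$bank, ob$tvc, ob$fitc,
                          gate_bin = cfg$gate_bin)
      r$scene_id <- id
      r$diagnostics <- r$diagnostics[c("iterations", "rel_change")]
      r
    })
    saveRDS(list(config_hash = hash, results = recons), paths$tvrecon)
  })

  if ("train" %in% stages) t_stage("train", {
    train_scenes <- make_dataset(cfg$n_train, "train", level = cfg$level,
                                 rng_seed = seeds[["phantoms"]])
    val_scenes <- make_dataset(cfg$n_val, "val", level = cfg$level,
                               rng_seed = seeds[["phantoms"]])
    tr <- net_training_set(train_scenes, ob$bank, ob$irf, ob$axis, ob$netc,
                           rng_seed = seeds[["training"]])
    va <- net_training_set(val_scenes, ob$bank, ob$irf, ob$axis, ob$netc,
                           rng_seed = seeds[["training"]] + 1L)
    model <- train_netflics(build_model(ob$netc), tr, va, verbose = verbose)
    save_model(model, paths$model)
  })

  if ("predict" %in% stages) t_stage("predict", {
    need(paths$dataset, "predict", "simulate")
    need(paths$model, "predict", "train")
    ds <- read_dataset(paths$dataset)
    model <- load_model(paths$model)
    meas <- ds$measurements[ds$scene_ids]
    res <- predict_netflics(model, unname(meas))
    for (i in seq_along(res)) res[[i]]$scene_id <- ds$scene_ids[i]
    saveRDS(list(config_hash = hash, results = res), paths$netflics)
  })

  if ("evaluate" %in% stages) t_stage("evaluate", {
    need(paths$dataset, "evaluate", "simulate")
    ds <- read_dataset(paths$dataset)
    truths <- unname(ds$scenes[ds$scene_ids])
    found <- FALSE
    for (method in c("tvrecon", "netflics")) {
      p <- paths[[method]]
      if (file.exists(p)) {
        found <- TRUE
        rep <- evaluate_recon(readRDS(p)$results, truths)
        write_eval_report(rep, file.path(out_dir, paste0("report_", method)))
        paths[[paste0("report_", method)]] <- file.path(
          out_dir, paste0("report_", method, c(".csv", ".json")))
      }
    }
    if (!found)
      stop("stage 'evaluate' needs the artifact of stage 'tvrecon' or 'predict'")
  })

  invisible(c(paths, config_hash = hash))
}
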