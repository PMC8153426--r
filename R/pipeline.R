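# Configuration-driven orchestration: a YAML/list config names an ordered
# set of stages; each stage consumes the shared state produced by earlier
# stages and contributes a summary to the JSON run report.

pipeline_stages <- function() {
  list(
    synth_tolerance = stage_synth_tolerance,
    cfu = stage_cfu,
    tolerance = stage_tolerance,
    synth_mst = stage_synth_mst,
    mst = stage_mst,
    synth_itc = stage_synth_itc,
    itc = stage_itc
  )
}

stage_synth_tolerance <- function(params, state, seed) {
  p <- utils::modifyList(
    list(breakpoint_c0 = 2, decline_slope = -4, floor_frequency = 0,
         concentrations = 0:6, base_density = 2e8, n_replicates = 3),
    params)
  model <- tolerance_model(p$breakpoint_c0, p$decline_slope,
                           p$floor_frequency)
  state$spots <- sim_tolerance_counts(
    model, concentrations = p$concentrations,
    base_density = p$base_density, n_replicates = p$n_replicates,
    seed = seed)
  state$true_slope <- p$decline_slope
  list(state = state,
       summary = list(concentrations = p$concentrations,
                      true_slope = p$decline_slope))
}

stage_cfu <- function(params, state, seed) {
  if (is.null(state$spots)) {
    stop("stage `cfu` needs spot data (run `synth_tolerance` or load CSV)",
         call. = FALSE)
  }
  p <- utils::modifyList(list(countable_range = c(3, 150)), params)
  rows <- list()
  for (cc in names(state$spots)) {
    for (s in state$spots[[cc]]) {
      est <- estimate_cfu(s, countable_range = p$countable_range)
      rows[[length(rows) + 1L]] <- data.frame(
        concentration = as.numeric(cc), replicate = est$replicate_id,
        cfu = est$cfu_per_ml, censored = est$censored)
    }
  }
  state$cfu <- do.call(rbind, rows)
  list(state = state,
       summary = list(n_estimates = nrow(state$cfu),
                      baseline_mean =
                        mean(state$cfu$cfu[state$cfu$concentration == 0])))
}

stage_tolerance <- function(params, state, seed) {
  if (is.null(state$cfu)) {
    stop("stage `tolerance` needs CFU estimates (run `cfu` first)",
         call. = FALSE)
  }
  p <- utils::modifyList(list(selection = "last_k_nonzero", k = 4), params)
  curve <- frequency_curve(state$cfu)
  fit <- decline_slope(curve, selection = p$selection, k = p$k)
  state$curve <- curve
  state$slope_fit <- fit
  list(state = state,
       summary = list(slope = fit$slope, slope_se = fit$slope_se,
                      n_points = fit$n_points))
}

stage_synth_mst <- function(params, state, seed) {
  p <- utils::modifyList(
    list(F_min = 850, F_max = 900, Kd = 8.01, n = 1,
         concentrations = 100 / 2^(0:15), noise_sd = 1, n_replicates = 3),
    params)
  state$mst <- sim_mst_curve(
    hill_model(p$F_min, p$F_max, p$Kd, p$n),
    concentrations = p$concentrations, noise_sd = p$noise_sd,
    n_replicates = p$n_replicates, seed = seed)
  list(state = state, summary = list(true_Kd = p$Kd, n_points = nrow(state$mst)))
}

stage_mst <- function(params, state, seed) {
  if (is.null(state$mst)) {
    stop("stage `mst` needs dose-response data (run `synth_mst` or load CSV)",
         call. = FALSE)
  }
  fit <- fit_hill(state$mst$concentration, state$mst$F_norm)
  state$mst_fit <- fit
  list(state = state,
       summary = list(Kd = fit$estimate$Kd, Kd_se = unname(fit$se[["Kd"]]),
                      n = fit$estimate$n))
}

stage_synth_itc <- function(params, state, seed) {
  p <- utils::modifyList(
    list(Kd = 8, dH = -22.65, n_sites = 1, dilution_heat = -2,
         noise_sd = 0.25),
    params)
  state$itc <- sim_itc_thermogram(
    itc_protocol(), n_sites = p$n_sites, Kd = p$Kd, dH = p$dH,
    dilution_heat = p$dilution_heat, noise_sd = p$noise_sd, seed = seed)
  list(state = state, summary = list(true_dH = p$dH, true_Kd = p$Kd))
}

stage_itc <- function(params, state, seed) {
  if (is.null(state$itc)) {
    stop("stage `itc` needs thermogram data (run `synth_itc` or load CSV)",
         call. = FALSE)
  }
  p <- utils::modifyList(list(fix_n = 1), params)
  corrected <- subtract_blank(state$itc)
  fit <- fit_itc(corrected, state$itc$protocol, fix_n = p$fix_n)
  state$itc_fit <- fit
  list(state = state,
       summary = list(dH = fit$estimate$dH, Kd = fit$estimate$Kd,
                      dH_se = unname(fit$se[["dH"]])))
}

#' Run a configured analysis pipeline
#'
#' Executes the configured stages in order over a shared state, collecting a
#' per-stage summary into a JSON-serializable run report.  The stage
#' vocabulary is `synth_tolerance`, `cfu`, `tolerance`, `synth_mst`, `mst`,
#' `synth_itc`, `itc`; unknown stage names fail validation before anything
#' executes.  A failed stage is recorded as `failed` and all later stages
#' are skipped (state dependencies make later stages unreliable).  Two runs
#' with the same config produce identical report payloads apart from the
#' `timestamp` field.
#'
#' @param config A list, or path to a YAML file, with fields `seed`
#'   (integer), optional `output_dir`, and `stages`: a list whose elements
#'   are either stage-name strings or lists with `name` and `params`.
#' @return The run report (list of class `pipeline_report`), invisibly
#'   written to `<output_dir>/report.json` when `output_dir` is set.
#' @examples
#' cfg <- list(seed = 1, stages = list("synth_tolerance", "cfu", "tolerance"))
#' rep <- run_pipeline(cfg)
#' rep$stages$tolerance$summary$slope
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or YAML path",
                             call. = FALSE)
  seed <- check_seed(config$seed)
  stages <- config$stages
  if (is.null(stages)) stages <- list()
  norm <- lapply(stages, function(s) {
    if (is.character(s)) list(name = s, params = list())
    else if (is.list(s) && !is.null(s$name)) {
      list(name = s$name, params = if (is.null(s$params)) list() else s$params)
    } else stop("each stage must be a name or a list with `name`",
                call. = FALSE)
  })
  registry <- pipeline_stages()
  unknown <- setdiff(vapply(norm, `[[`, character(1), "name"),
                     names(registry))
  if (length(unknown)) {
    stop("unknown pipeline stage(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  state <- list()
  report_stages <- list()
  failed <- FALSE
  for (i in seq_along(norm)) {
    nm <- norm[[i]]$name
    if (failed) {
      report_stages[[nm]] <- list(status = "skipped")
      next
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      out <- registry[[nm]](norm[[i]]$params, state, seed + i)
      state <- out$state
      list(status = "ok", summary = out$summary,
           elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    }, error = function(e) {
      list(status = "failed", error = conditionMessage(e))
    })
    if (res$status == "failed") failed <- TRUE
    report_stages[[nm]] <- res
    message(sprintf("[pipeline] %-16s %s", nm, res$status))
  }

  report <- list(
    package = "formstress",
    version = as.character(utils::packageVersion("formstress")),
    seed = seed,
    n_stages = length(norm),
    stages = report_stages,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  class(report) <- c("pipeline_report", class(report))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(state$cfu)) {
      utils::write.csv(state$cfu,
                       file.path(config$output_dir, "cfu_estimates.csv"),
                       row.names = FALSE)
    }
    if (!is.null(state$curve)) {
      utils::write.csv(as.data.frame(state$curve),
                       file.path(config$output_dir, "tolerance_curve.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(unclass(report),
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> formstress %s, seed %d\n", x$version,
              x$seed))
  for (nm in names(x$stages)) {
    cat(sprintf("  %-16s %s\n", nm, x$stages[[nm]]$status))
  }
  invisible(x)
}
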