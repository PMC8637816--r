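# Report pipeline tying the stages together: summary statistics, limit
# check, deterministic risk at the panel mean, zero-inflated lognormal fit,
# Monte Carlo risk percentiles, the blood-lead scenario grid, and the child
# lip intake. All outputs are plain CSV plus a JSON manifest recording
# every parameter and seed needed to regenerate them.

#' Configuration for the full report pipeline
#'
#' Exactly one concentration source must be given: either a panel CSV
#' (`panel_file`) or a synthetic [panel_spec()] (`synthetic_spec`).
#'
#' @param panel_file path to a panel CSV in the [read_panel()] schema.
#' @param synthetic_spec a [panel_spec()] to generate the panel from.
#' @param out_dir output directory (created if missing).
#' @param mc an [mc_config()] for the Monte Carlo stage.
#' @param alm an [alm_params()] set; by default the panel's overall mean
#'   concentration replaces the lip-cosmetic term input.
#' @param limit_mg_per_kg regulatory limit for the compliance check.
#' @param rounding rounding mode for the blood-lead grid.
#' @return A `run_config` list.
#' @export
run_config <- function(panel_file = NULL, synthetic_spec = NULL,
                       out_dir = tempfile("liprisk_report_"),
                       mc = mc_config(), alm = NULL,
                       limit_mg_per_kg = 10,
                       rounding = c("full_precision", "paper_emulation")) {
  if (is.null(panel_file) == is.null(synthetic_spec)) {
    stop_liprisk("give exactly one of panel_file or synthetic_spec",
                 "liprisk_parameter_error")
  }
  structure(list(panel_file = panel_file, synthetic_spec = synthetic_spec,
                 out_dir = out_dir, mc = mc, alm = alm,
                 limit_mg_per_kg = limit_mg_per_kg,
                 rounding = match.arg(rounding)),
            class = "run_config")
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_liprisk(sprintf("pipeline stage '%s' failed: %s", stage,
                         conditionMessage(e)),
                 "liprisk_pipeline_error")
  })
}

#' Run the full exposure and risk report pipeline
#'
#' Executes, in order: panel load or synthesis, category summary, regulatory
#' limit check, deterministic risk at the panel mean for both user presets,
#' zero-inflated lognormal fit, Monte Carlo percentile risk, the blood-lead
#' scenario grid with maternal input means, and the child lip-balm intake.
#' Writes one CSV per section plus `manifest.json` under `cfg$out_dir`.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with every section's in-memory result and
#'   `manifest` (also written to `manifest.json`).
#' @export
#' @examples
#' cfg <- run_config(synthetic_spec = panel_spec(seed = 1),
#'                   mc = mc_config(n_iter = 500, seed = 1))
#' res <- run_pipeline(cfg)
#' names(res)
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  panel <- pipeline_stage("load_panel", {
    if (!is.null(cfg$panel_file)) {
      if (!file.exists(cfg$panel_file)) {
        stop(sprintf("panel file not found: %s", cfg$panel_file))
      }
      read_panel(cfg$panel_file)
    } else {
      generate_panel(cfg$synthetic_spec)
    }
  })

  summary_tbl <- pipeline_stage("summarize", summarize_panel(panel))
  limit <- pipeline_stage("limit_check",
                          check_limit(panel, cfg$limit_mg_per_kg))

  mean_conc <- summary_tbl$mean[summary_tbl$group == "total"]
  presets <- list(average_user = exposure_params("average_user"),
                  high_user = exposure_params("high_user"))
  det_risk <- pipeline_stage("deterministic_risk", {
    out <- do.call(rbind, lapply(names(presets), function(nm) {
      cbind(preset = nm, assess_risk(mean_conc, presets[[nm]]))
    }))
    tibble::as_tibble(out)
  })

  fit <- pipeline_stage("fit",
    fit_concentration_distribution(panel$pb_mg_per_kg))
  mc <- pipeline_stage("monte_carlo",
    probabilistic_risk(fit, presets, cfg$mc))

  alm <- if (is.null(cfg$alm)) alm_params(PbL = mean_conc) else cfg$alm
  grid <- pipeline_stage("blood_lead",
    scenario_table(alm, rounding = cfg$rounding))
  maternal <- pipeline_stage("maternal_inputs",
    maternal_input_mean(grid$fetal))

  balm_mean <- summary_tbl$mean[summary_tbl$group == "lip_balm"]
  balm_max <- summary_tbl$max[summary_tbl$group == "lip_balm"]
  child <- pipeline_stage("child_intake", {
    if (length(balm_mean) == 0L) {
      tibble::tibble(condition = character(0), intake_ug_per_d = numeric(0))
    } else {
      tibble::tibble(
        condition = c("average_exposure", "high_exposure"),
        intake_ug_per_d = c(
          child_lip_intake(balm_mean, exposure_params("average_user")$IR),
          child_lip_intake(balm_max, exposure_params("high_user")$IR))
      )
    }
  })

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out_csv <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    path
  }
  files <- c(
    summary = out_csv(summary_tbl, "panel_summary.csv"),
    limit_flags = out_csv(limit$flags, "limit_check.csv"),
    deterministic_risk = out_csv(det_risk, "deterministic_risk.csv"),
    mc_summary = out_csv(mc$summary, "mc_percentiles.csv"),
    bll_totals = out_csv(grid$totals, "bll_scenario_totals.csv"),
    bll_fetal = out_csv(grid$fetal, "bll_scenario_fetal.csv"),
    child_intake = out_csv(child, "child_lip_intake.csv")
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("liprisk")),
    source = if (!is.null(cfg$panel_file)) {
      list(type = "file", path = cfg$panel_file)
    } else {
      list(type = "synthetic", spec = unclass(cfg$synthetic_spec))
    },
    n_records = nrow(panel),
    limit_mg_per_kg = cfg$limit_mg_per_kg,
    limit_verdict = limit$verdict,
    mean_concentration_mg_per_kg = mean_conc,
    fit = unclass(fit),
    mc = list(n_iter = mc$n_iter, seed = mc$seed,
              percentiles = mc$percentiles),
    alm = unclass(alm),
    rounding = cfg$rounding,
    maternal_inputs_ug_per_dl = as.list(maternal),
    files = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(panel = panel, summary = summary_tbl, limit = limit,
                 deterministic_risk = det_risk, fit = fit, mc = mc,
                 bll = grid, maternal_inputs = maternal, child = child,
                 manifest = manifest, out_dir = cfg$out_dir))
}
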