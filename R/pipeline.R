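#' Pipeline run configuration
#'
#' Validates and normalizes the configuration driving [run_pipeline()]:
#' the input source (a [generator_config()] for a synthetic run, or a
#' cohort CSV path), the analysis block (summary variables, model
#' formulas, candidate variables for the index comparison, alpha), the
#' index options, the output directory and the run seed. Can also be
#' loaded from a YAML file.
#'
#' @param input either a `generator_config` (synthetic run) or a list
#'   `list(file = "path/to/cohort.csv")`.
#' @param out_dir output directory for the report bundle.
#' @param seed integer run seed; stage seeds are derived from it.
#' @param alpha significance level for comparison cells.
#' @param summary_variables character vector of columns for the grouped
#'   summary tables (sensible cohort defaults if NULL).
#' @param model_formulas named list with `al` and `csi` model formulas
#'   (as character).
#' @param candidates candidate variables for the comparison matrix.
#' @param correlation_variables continuous columns for the Pearson matrix.
#' @param categorical_variables columns for the Cramer's V matrix.
#' @param vif_predictors predictor columns for the VIF table.
#' @param efa_max_factors scan depth for the factor-number table.
#' @param cutoff_weighting passed to the index specs.
#' @param lonely_psu passed to all estimators.
#' @param log_level "debug", "info" or "warn".
#' @return validated object of class `run_config`.
#' @export
run_config <- function(input = generator_config(),
                       out_dir = "stressindex_run",
                       seed = 1L,
                       alpha = 0.05,
                       summary_variables = NULL,
                       model_formulas = list(
                         al = "al_high ~ age + sex + poverty_status + alcohol + smoker + loa",
                         csi = "csi_high ~ age + sex + alcohol + smoker + loa"),
                       candidates = NULL,
                       correlation_variables = NULL,
                       categorical_variables = NULL,
                       vif_predictors = NULL,
                       efa_max_factors = 4L,
                       cutoff_weighting = "unweighted",
                       lonely_psu = "fail",
                       log_level = "info") {
  if (alpha <= 0 || alpha >= 1) stop_named("alpha must lie in (0,1)")
  if (!inherits(input, "generator_config")) {
    if (!is.list(input) || is.null(input$file)) {
      stop_named("input must be a generator_config or list(file = path)")
    }
    if (!file.exists(input$file)) {
      stop_named("input file does not exist: %s", input$file)
    }
  }
  cfg <- list(
    input = input, out_dir = out_dir, seed = as.integer(seed),
    alpha = alpha,
    summary_variables = summary_variables %||%
      c("age", "sex", "race_ethnicity", "income_bracket", "education",
        "physical_activity", "alcohol", "smoker"),
    model_formulas = model_formulas,
    candidates = candidates %||%
      c("age", "sex", "race_ethnicity", "health_status", "coa", "loa",
        "latent_high"),
    correlation_variables = correlation_variables %||%
      c("age", "hdl", "tg", "albumin", "clcr", "crp"),
    categorical_variables = categorical_variables %||%
      c("csi_risk", "al_risk", "sex", "smoker", "alcohol", "coa", "loa",
        "health_status"),
    vif_predictors = vif_predictors %||%
      c("age", "sex", "alcohol", "smoker", "loa"),
    efa_max_factors = as.integer(efa_max_factors),
    cutoff_weighting = cutoff_weighting,
    lonely_psu = lonely_psu,
    log_level = match.arg(log_level, c("debug", "info", "warn")))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; recognized keys mirror the [run_config()]
#'   arguments, with `input: synthetic: {...}` taken as generator-config
#'   fields and `input: file: path` as a cohort CSV.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  input <- if (!is.null(raw$input$synthetic)) {
    do.call(generator_config, raw$input$synthetic)
  } else if (!is.null(raw$input$file)) {
    list(file = raw$input$file)
  } else {
    generator_config()
  }
  args <- raw[setdiff(names(raw), "input")]
  do.call(run_config, c(list(input = input), args))
}

log_line <- function(level, cfg, stage, fmt, ..., con = NULL) {
  levels_rank <- c(debug = 1, info = 2, warn = 3)
  msg <- sprintf("[%s] %s: %s", level, stage, sprintf(fmt, ...))
  if (levels_rank[level] >= levels_rank[cfg$log_level]) {
    message(msg)
  }
  if (!is.null(con)) writeLines(msg, con)
  invisible(msg)
}

#' Run the full index-construction and comparison pipeline
#'
#' Executes generate/ingest, recode, index construction (CSI and AL),
#' and the full analysis battery, writing a report bundle to the output
#' directory: quartile cutoffs, per-participant index tables, grouped
#' summary tables by AL and CSI risk, Pearson and Cramer's V association
#' matrices, the VIF table, odds-ratio tables for both logistic models,
#' the AL-vs-CSI comparison matrix, the EFA factor-number scan, and a
#' machine-readable JSON manifest (config hash, seed, per-stage n, and
#' the provenance of every reported p-value). Identical config + seed
#' give byte-identical outputs. Any stage failure aborts with the stage
#' name.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logcon <- file(log_path, open = "wt")
  on.exit(close(logcon), add = TRUE)
  artifacts <- character(0)
  stage_n <- list()
  provenance <- list()

  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      log_line("warn", config, stage, "FAILED: %s", conditionMessage(e),
               con = logcon)
      stop_named("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e))
    })
    log_line("info", config, stage, "done (%.2fs)",
             proc.time()[["elapsed"]] - t0, con = logcon)
    res
  }

  emit_csv <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    artifacts <<- c(artifacts, name)
    path
  }
  emit_text <- function(lines, name) {
    path <- file.path(config$out_dir, name)
    writeLines(lines, path)
    artifacts <<- c(artifacts, name)
    path
  }

  # --- ingest -------------------------------------------------------------
  bundle <- run_stage("ingest", {
    if (inherits(config$input, "generator_config")) {
      gcfg <- config$input
      gcfg$seed <- derive_seed(config$seed, "generate")
      generate_cohort(gcfg)
    } else {
      cohort <- utils::read.csv(config$input$file,
                                stringsAsFactors = FALSE)
      for (col in c("stratum", "psu", "weight")) {
        if (is.null(cohort[[col]])) {
          stop_named("cohort file lacks design column '%s'", col)
        }
      }
      list(cohort = cohort,
           design = svy_design(cohort$stratum, cohort$psu, cohort$weight),
           truth = NULL)
    }
  })
  cohort <- bundle$cohort
  design <- bundle$design
  stage_n$ingest <- nrow(cohort)

  # --- recode -------------------------------------------------------------
  cohort <- run_stage("recode", recode_all(cohort))
  stage_n$recode <- nrow(cohort)

  # --- indices ------------------------------------------------------------
  idx <- run_stage("index", {
    csi <- suppressMessages(build_index_table(
      cohort, csi_spec(cutoff_weighting = config$cutoff_weighting),
      design))
    al <- suppressMessages(build_index_table(
      cohort, al_spec(cutoff_weighting = config$cutoff_weighting),
      design))
    list(csi = csi, al = al)
  })
  cohort$csi_score <- idx$csi$index$csi_score
  cohort$csi_risk <- idx$csi$index$csi_risk
  cohort$al_score <- idx$al$index$al_score
  cohort$al_risk <- idx$al$index$al_risk
  cohort$csi_high <- as.integer(cohort$csi_risk == "high")
  cohort$al_high <- as.integer(cohort$al_risk == "high")
  stage_n$csi_complete <- sum(idx$csi$index$csi_complete)
  stage_n$al_complete <- sum(idx$al$index$al_complete)
  log_line("info", config, "index", "CSI n = %d, AL n = %d",
           stage_n$csi_complete, stage_n$al_complete, con = logcon)

  cutoffs <- rbind(cbind(index = "CSI", idx$csi$cutoffs),
                   cbind(index = "AL", idx$al$cutoffs))
  emit_csv(cutoffs, "cutoffs.csv")
  emit_csv(merge(idx$csi$index, idx$al$index, by = "participant_id"),
           "index_scores.csv")

  # --- analysis -----------------------------------------------------------
  analysis <- run_stage("analyze", {
    out <- list()
    for (index in c("al", "csi")) {
      risk <- cohort[[paste0(index, "_risk")]]
      keep <- !is.na(risk)
      gs <- grouped_summary(cohort[keep, , drop = FALSE], risk[keep],
                            config$summary_variables,
                            design_subset(design, keep),
                            config$lonely_psu)
      out[[paste0("summary_", index)]] <- gs
      for (v in unique(gs$variable)) {
        provenance[[length(provenance) + 1]] <- list(
          table = paste0("summary_", index), variable = v,
          test = gs$type[gs$variable == v][1],
          p = gs$p[gs$variable == v][1],
          n = sum(gs$n[gs$variable == v]),
          df_design = degf(design_subset(design, keep)))
      }
    }
    out$pearson <- correlation_matrix(
      cohort, c(config$correlation_variables, "csi_high", "al_high"),
      method = "pearson")
    out$cramers_v <- correlation_matrix(
      cohort, config$categorical_variables, method = "cramers_v")
    out$vif <- vif(cohort, config$vif_predictors)
    out
  })
  emit_csv(analysis$summary_al, "summary_al.csv")
  emit_csv(analysis$summary_csi, "summary_csi.csv")
  emit_csv(as.data.frame(analysis$pearson$matrix), "correlation_pearson.csv")
  emit_csv(as.data.frame(analysis$cramers_v$matrix), "cramers_v.csv")
  emit_csv(analysis$vif, "vif.csv")
  emit_text(format_summary_text(analysis$summary_al, "AL risk"),
            "summary_al.txt")
  emit_text(format_summary_text(analysis$summary_csi, "CSI risk"),
            "summary_csi.txt")

  # --- models -------------------------------------------------------------
  fits <- run_stage("models", {
    lapply(stats::setNames(names(config$model_formulas),
                           names(config$model_formulas)), function(nm) {
      f <- stats::as.formula(config$model_formulas[[nm]])
      fit <- fit_survey_logistic(f, cohort, design,
                                 lonely_psu = config$lonely_psu)
      for (term in setdiff(fit$terms, "(Intercept)")) {
        provenance[[length(provenance) + 1]] <<- list(
          table = paste0("odds_ratios_", nm), variable = term,
          test = "survey logistic t", p = unname(fit$p[term]),
          n = fit$n, df_design = fit$df_design)
      }
      fit
    })
  })
  for (nm in names(fits)) {
    ort <- odds_ratio_table(fits[[nm]])
    ort$aic <- attr(ort, "aic")
    emit_csv(ort, sprintf("odds_ratios_%s.csv", nm))
    emit_text(format_or_text(fits[[nm]], toupper(nm)),
              sprintf("odds_ratios_%s.txt", nm))
  }

  # --- comparison ---------------------------------------------------------
  comparison <- run_stage("compare", {
    compare_indices(cohort, design, config$candidates, fits = fits,
                    alpha = config$alpha, lonely_psu = config$lonely_psu)
  })
  for (i in seq_len(nrow(comparison))) {
    provenance[[length(provenance) + 1]] <- list(
      table = "comparison_matrix", variable = comparison$candidate[i],
      index = comparison$index[i], test = comparison$method[i],
      p = comparison$p[i], n = comparison$n[i],
      df_design = degf(design))
  }
  emit_csv(comparison, "comparison_matrix.csv")

  # --- EFA ----------------------------------------------------------------
  efa <- run_stage("efa", {
    out <- list()
    for (index in c("csi", "al")) {
      compcols <- grep(paste0("^", index, "_c_"),
                       names(idx[[index]]$index), value = TRUE)
      comp <- idx[[index]]$index[idx[[index]]$index[[
        paste0(index, "_complete")]], compcols]
      scan <- factor_number_scan(comp, config$efa_max_factors,
                                 seed = derive_seed(config$seed, "efa"))
      out[[index]] <- cbind(index = toupper(index), scan$summary)
    }
    do.call(rbind, out)
  })
  emit_csv(efa, "efa_scan.csv")
  emit_text(format_efa_text(efa), "efa_scan.txt")

  # --- manifest -----------------------------------------------------------
  manifest <- list(
    package = "stressindex",
    version = as.character(utils::packageVersion("stressindex")),
    seed = config$seed,
    config_hash = fnv1a32(yaml::as.yaml(serialize_config(config))),
    alpha = config$alpha,
    stage_n = stage_n,
    artifacts = sort(unique(artifacts)),
    provenance = provenance)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("info", config, "report", "wrote %d artifacts to %s",
           length(artifacts) + 1, config$out_dir, con = logcon)
  invisible(manifest)
}

serialize_config <- function(config) {
  out <- unclass(config)
  if (inherits(out$input, "generator_config")) {
    out$input <- config_to_list(out$input)
  }
  # the fingerprint covers the scientific configuration, not where the
  # bundle lands or how chatty the log is
  out$out_dir <- NULL
  out$log_level <- NULL
  out
}

# aligned-text rendering of a grouped summary (estimate (SE) / proportion
# rows with a p column)
format_summary_text <- function(gs, group_label) {
  fmt_row <- function(r) {
    if (r$type == "continuous") {
      sprintf("%-28s %18s %18s %18s %8s",
              r$variable,
              sprintf("%.2f (%.2f)", r$overall, r$overall_se),
              sprintf("%.2f (%.2f)", r[[6]], r[[7]]),
              sprintf("%.2f (%.2f)", r[[8]], r[[9]]),
              format.pval(r$p, digits = 2, eps = 0.001))
    } else {
      sprintf("%-28s %18s %18s %18s %8s",
              paste0("  ", r$level),
              sprintf("%.2f%%", 100 * r$overall),
              sprintf("%.2f%%", 100 * r[[6]]),
              sprintf("%.2f%%", 100 * r[[8]]),
              "")
    }
  }
  lines <- c(sprintf("Grouped summary by %s", group_label),
             sprintf("%-28s %18s %18s %18s %8s", "Characteristic",
                     "Overall", names(gs)[6], names(gs)[8], "p"))
  prev_var <- ""
  for (i in seq_len(nrow(gs))) {
    r <- gs[i, ]
    if (r$type == "categorical" && r$variable != prev_var) {
      lines <- c(lines,
                 sprintf("%-28s %56s %8s", r$variable, "",
                         format.pval(r$p, digits = 2, eps = 0.001)))
    }
    lines <- c(lines, fmt_row(r))
    prev_var <- r$variable
  }
  lines
}

format_or_text <- function(fit, label) {
  ort <- odds_ratio_table(fit)
  lines <- c(sprintf("Logistic regression model of %s risk", label),
             sprintf("%-28s %24s %10s", "Characteristic",
                     "OR (2.5%, 97.5%)", "p"))
  for (i in seq_len(nrow(ort))) {
    r <- ort[i, ]
    if (isTRUE(r$reference)) {
      lines <- c(lines, sprintf("%-28s %24s %10s", r$term, "Reference", ""))
    } else {
      lines <- c(lines, sprintf(
        "%-28s %24s %10s", r$term,
        sprintf("%.2f (%.2f, %.2f)", r$or, r$ci_low, r$ci_high),
        format.pval(r$p, digits = 2, eps = 0.001)))
    }
  }
  c(lines, sprintf("AIC %.2f", attr(ort, "aic")))
}

format_efa_text <- function(efa) {
  lines <- "EFA factor-number scan (ML, unrotated)"
  for (index in unique(efa$index)) {
    sub <- efa[efa$index == index, ]
    star <- ifelse(sub$reject, " *", "")
    lines <- c(lines, sprintf("%s:", index),
               paste0("  Number of factors:   ",
                      paste(sprintf("%d%s", sub$n_factors, star),
                            collapse = "   ")),
               paste0("  SS loadings:         ",
                      paste(sprintf("%.3f", sub$ss_loading),
                            collapse = "   ")),
               paste0("  Cumulative variance: ",
                      paste(sprintf("%.3f", sub$cumulative_variance),
                            collapse = "   ")))
  }
  c(lines, "  * chi-square test of the number of factors, p < 0.05")
}
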