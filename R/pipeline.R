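#' Pipeline configuration
#'
#' One flat configuration object drives the whole analysis; no stage has
#' hidden defaults outside it.  Conventions recorded here so they are
#' auditable: quantile type 7 (linear interpolation between order
#' statistics) for the thermal trait derivation, `log(x + 1)` for the two
#' latency-type traits, right-censoring value 3600 s for risk-taking.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Master seed (mandatory; every stochastic stage derives its
#'   own stream from it).
#' @param simulate Generate the raw logs (`TRUE`) or read them from
#'   `raw_paths` (`FALSE`).
#' @param raw_paths Named list of input paths (`thermal_log`,
#'   `behaviour_log`, `covariates`) used when `simulate = FALSE`.
#' @param traits Traits to analyse (default all six).
#' @param dhmm_covariates Covariate columns for the per-trait models; the
#'   default is the full state-covariate set, `character(0)` gives the
#'   intercept-plus-time variant.
#' @param dhmm_args,mv_args Lists of extra arguments passed to
#'   [sample_dhmm()] and [fit_multitrait()] (e.g. `scale`, `iter`).
#' @param quantile_type,log_offset,censor_s Derivation conventions (see
#'   above).
#' @param prob Credible mass for all intervals.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("thermopred_run_"),
                            seed,
                            simulate = TRUE,
                            raw_paths = NULL,
                            traits = c("t_sel", "t_set", "t_vmax",
                                       "activity", "sheltering",
                                       "risk_taking"),
                            dhmm_covariates = c("svl_z", "rel_head_z",
                                                "condition_z", "parasite_z",
                                                "svl_parasite_z",
                                                "rel_head_parasite_z",
                                                "condition_parasite_z"),
                            dhmm_args = list(scale = "desk"),
                            mv_args = list(scale = "desk"),
                            quantile_type = 7L, log_offset = 1,
                            censor_s = 3600, prob = 0.95) {
  if (missing(seed)) stop("a seed is mandatory: every stochastic stage ",
                          "derives its stream from it")
  if (!simulate) {
    need <- c("thermal_log", "behaviour_log", "covariates")
    if (is.null(raw_paths) || !all(need %in% names(raw_paths))) {
      stop("simulate = FALSE requires raw_paths with: ",
           paste(need, collapse = ", "))
    }
    if (anyDuplicated(unlist(raw_paths))) stop("raw_paths must be distinct")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, raw_paths = raw_paths, traits = traits,
                 dhmm_covariates = dhmm_covariates, dhmm_args = dhmm_args,
                 mv_args = mv_args, quantile_type = quantile_type,
                 log_offset = log_offset, censor_s = censor_s, prob = prob),
            class = "pipeline_config")
}

#' Read a delimited table with schema validation
#'
#' Reads a header-bearing tab-delimited table, checks that every declared
#' column is present (error naming the missing column), validates numeric
#' columns cell by cell (error carrying the offending row number), converts
#' declared columns to their types and preserves undeclared columns.
#' Missing values are encoded as empty fields.
#'
#' @param path File path.
#' @param schema Optional named character vector mapping column names to
#'   `"numeric"`, `"integer"`, `"character"` or `"logical"`.
#' @return Tibble.
#' @export
read_table <- function(path, schema = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), na = "", progress = FALSE)
  if (!is.null(schema)) {
    miss <- setdiff(names(schema), names(raw))
    if (length(miss)) {
      stop("declared column(s) missing from ", path, ": ",
           paste(miss, collapse = ", "))
    }
    for (cl in names(schema)) {
      x <- raw[[cl]]
      if (schema[[cl]] %in% c("numeric", "integer")) {
        bad <- which(!is.na(x) & is.na(suppressWarnings(as.numeric(x))))
        if (length(bad)) {
          stop("non-numeric value in numeric column '", cl, "' at row ",
               bad[1], ": '", x[bad[1]], "'")
        }
        raw[[cl]] <- if (schema[[cl]] == "integer") as.integer(x) else
          as.numeric(x)
      } else if (schema[[cl]] == "logical") {
        raw[[cl]] <- as.logical(x)
      }
    }
    rest <- setdiff(names(raw), names(schema))
  } else {
    rest <- names(raw)
  }
  for (cl in rest) {
    raw[[cl]] <- utils::type.convert(raw[[cl]], as.is = TRUE)
  }
  raw
}

#' Write a delimited table
#'
#' Tab-delimited, header row, UTF-8, missing values as empty fields, numeric
#' values at full (round-trippable) precision.
#'
#' @param records Data frame / tibble.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  readr::write_tsv(records, path, na = "", progress = FALSE)
  invisible(path)
}

.report_labels <- c(
  beta0 = "Intercept", time = "Time", sd_intercept = "sd_Intercept",
  sd_time = "sd_Time", r_intercept_slope = "r_Intercept-Slope",
  gamma0 = "Intercept (residual)", omega = "omega_Intercept",
  r_intercept_omega = "r_Intercept-omega.Intercept",
  r_slope_omega = "r_Slope-omega.Intercept")

.relabel_params <- function(summary_tab) {
  p <- summary_tab$parameter
  p <- sub("^beta_time$", "Time", p)
  hit <- match(p, names(.report_labels))
  p[!is.na(hit)] <- .report_labels[hit[!is.na(hit)]]
  summary_tab$parameter <- p
  summary_tab
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional), derive, per-trait location-scale model
#' fits, derived personality/predictability statistics, the multivariate
#' between/within decomposition, and assembles a consolidated report.  Every
#' stage's outputs are written to `config$out_dir` before the next stage
#' begins.  A trait whose model fit fails (or fails to converge) appears in
#' the report with an explicit reason; it is never silently omitted.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `analysis_report`: `$trait_tables` (reporting-table-style
#'   posterior summaries per trait), `$repeatability`, `$predictability`
#'   (CV_P), `$type_predictability`, `$syndromes` (between/within
#'   correlation decomposition), `$convergence`, `$failures`,
#'   `$provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(config$out_dir, ...)

  # -- stage 1: raw data --------------------------------------------------
  if (config$simulate) {
    raw <- simulate_raw_dataset(sim_config(seed = config$seed))
    write_table(raw$thermal_log, pth("thermal_log.tsv"))
    write_table(raw$behaviour_log, pth("behaviour_log.tsv"))
    write_table(raw$covariates, pth("covariates.tsv"))
  } else {
    raw <- structure(list(
      thermal_log = read_table(config$raw_paths$thermal_log),
      behaviour_log = read_table(config$raw_paths$behaviour_log),
      covariates = read_table(config$raw_paths$covariates)),
      class = "raw_dataset")
  }

  # -- stage 2: trait derivation ------------------------------------------
  tab <- derive_trait_table(raw, censor_s = config$censor_s)
  write_table(tab, pth("trait_table.tsv"))

  # -- stage 3: per-trait location-scale fits -----------------------------
  trait_tables <- list()
  repeat_rows <- list()
  pred_rows <- list()
  tp_rows <- list()
  conv <- list()
  failures <- list()
  for (k in seq_along(config$traits)) {
    tr <- config$traits[k]
    fit <- tryCatch({
      spec <- dhmm_spec(paste0(tr, "_z"),
                        covariates = config$dhmm_covariates)
      do.call(sample_dhmm,
              c(list(data = tab, spec = spec, seed = config$seed + k),
                config$dhmm_args))
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      failures[[tr]] <- conditionMessage(fit)
      next
    }
    trait_tables[[tr]] <- .relabel_params(summary(fit, prob = config$prob))
    conv[[tr]] <- fit$convergence
    rp <- repeatability(fit, prob = config$prob)
    repeat_rows[[tr]] <- tibble::tibble(
      trait = tr, mean = rp$mean, hpd_low = rp$hpd[1], hpd_high = rp$hpd[2])
    pv <- cv_p(fit, prob = config$prob)
    pred_rows[[tr]] <- tibble::tibble(
      trait = tr, cv_p = pv$mean, hpd_low = pv$hpd[1], hpd_high = pv$hpd[2])
    tp_rows[[tr]] <- dplyr::bind_cols(
      tibble::tibble(trait = tr),
      type_predictability_correlation(fit, prob = config$prob))
    write_table(trait_tables[[tr]], pth(paste0("dhmm_", tr, ".tsv")))
  }
  for (tr in names(failures)) {
    trait_tables[[tr]] <- NULL
  }

  # -- stage 4: multivariate decomposition --------------------------------
  syndromes <- tryCatch({
    mv <- do.call(fit_multitrait,
                  c(list(data = tab, traits = paste0(config$traits, "_z"),
                         seed = config$seed + 1000L),
                    config$mv_args))
    decompose_correlations(mv, prob = config$prob)
  }, error = function(e) {
    failures[["multivariate"]] <<- conditionMessage(e)
    NULL
  })
  if (!is.null(syndromes)) write_table(syndromes, pth("syndromes.tsv"))

  report <- structure(list(
    trait_tables = trait_tables,
    repeatability = dplyr::bind_rows(repeat_rows),
    predictability = dplyr::bind_rows(pred_rows),
    type_predictability = dplyr::bind_rows(tp_rows),
    syndromes = syndromes,
    convergence = conv,
    failures = failures,
    provenance = list(
      config_hash = rlang::hash(config), seed = config$seed,
      package_version = as.character(utils::packageVersion("thermopred")),
      r_version = R.version.string, timestamp = format(Sys.time()))),
    class = "analysis_report")
  .write_report_text(report, pth("report.txt"))
  report
}

.fmt_ci_tab <- function(tab) {
  utils::capture.output(print(as.data.frame(tab), row.names = FALSE))
}

.write_report_text <- function(report, path) {
  out <- c("thermopred analysis report",
           strrep("=", 60),
           paste0("config hash: ", report$provenance$config_hash),
           paste0("seed: ", report$provenance$seed),
           paste0("package: thermopred ",
                  report$provenance$package_version, " / ",
                  report$provenance$r_version),
           "")
  for (tr in names(report$trait_tables)) {
    cv <- report$convergence[[tr]]
    out <- c(out, paste0("== ", tr, " (convergence ",
                         if (attr(cv, "pass")) "passed" else "FAILED", ") =="),
             .fmt_ci_tab(report$trait_tables[[tr]]), "")
  }
  add <- function(title, tab) {
    if (!is.null(tab) && nrow(tab)) c(paste0("== ", title, " =="),
                                      .fmt_ci_tab(tab), "")
  }
  out <- c(out,
           add("Repeatability", report$repeatability),
           add("Coefficient of predictability (CV_P)",
               report$predictability),
           add("Behavioural type vs predictability correlations",
               report$type_predictability),
           add("Between/within-individual correlations",
               report$syndromes))
  if (length(report$failures)) {
    out <- c(out, "== Failures ==",
             vapply(names(report$failures), function(nm) {
               paste0(nm, ": ", report$failures[[nm]])
             }, character(1)))
  }
  writeLines(out, path)
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("thermopred analysis report\n")
  cat("  traits analysed:", length(x$trait_tables), "\n")
  if (length(x$failures)) {
    cat("  FAILURES:", paste(names(x$failures), collapse = ", "), "\n")
  }
  if (!is.null(x$syndromes)) {
    sb <- x$syndromes[x$syndromes$level == "between" &
                        x$syndromes$syndrome_flag, ]
    cat("  behavioural syndromes flagged:",
        if (nrow(sb)) paste(sb$trait_pair, collapse = ", ") else "none",
        "\n")
  }
  invisible(x)
}
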