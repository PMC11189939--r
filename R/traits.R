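#' Derive thermal traits from one individual-day temperature series
#'
#' From an ordered series of body temperatures recorded along the thermal
#' gradient, computes the three thermoregulatory descriptors: the selected
#' body temperature `t_sel` (median, the "goal" of thermoregulation), the
#' voluntary thermal maximum `t_vmax` (highest temperature reached, a
#' thermal-tolerance proxy) and the set-point range width `t_set` (span of
#' the central 50% of readings, a precision measure; smaller = more precise).
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), the convention recorded in
#' [pipeline_config()].
#'
#' @param temps Numeric vector of body temperatures (degrees C), at least 4
#'   finite values.
#' @return Named list with `t_sel`, `t_set`, `t_vmax`.
#' @examples
#' derive_thermal_traits(c(28, 30, 32, 34, 36))
#' @export
derive_thermal_traits <- function(temps) {
  if (!is.numeric(temps) || length(temps) < 4L) {
    stop("need at least 4 temperature readings to define quartiles")
  }
  if (any(!is.finite(temps))) stop("temperature readings must be finite")
  q <- unname(quantile(temps, c(0.25, 0.75), type = 7))
  list(t_sel = unname(median(temps)),
       t_set = q[2] - q[1],
       t_vmax = max(temps))
}

#' Derive behavioural traits from one trial record
#'
#' Movement activity is the per-minute grid-square transition rate while
#' outside the shelter, `(transitions / time_outside_s) * 60`, which makes it
#' independent of sheltering time.  Sheltering and risk-taking are returned
#' in seconds; the pipeline log-transforms them downstream (see
#' [standardize_traits()]).
#'
#' A record with zero time outside but a positive transition count is
#' internally inconsistent and rejected; with zero transitions as well, the
#' activity rate is undefined and returned as `NA`.
#'
#' @param sheltering_s Seconds spent hiding (0..3600).
#' @param transitions Grid-square transition count (non-negative integer).
#' @param time_outside_s Seconds outside the shelter (0..3600).
#' @param risk_latency_s Seconds until emergence after the simulated attack
#'   (non-negative; right-censored trials carry the trial length).
#' @return Named list with `activity` (per minute), `sheltering` (s),
#'   `risk_taking` (s).
#' @export
derive_behaviour_traits <- function(sheltering_s, transitions,
                                    time_outside_s, risk_latency_s) {
  if (sheltering_s < 0 || sheltering_s > 3600 ||
      time_outside_s < 0 || time_outside_s > 3600) {
    stop("sheltering_s and time_outside_s must lie in [0, 3600]")
  }
  if (transitions < 0 || transitions != round(transitions)) {
    stop("transitions must be a non-negative integer")
  }
  if (risk_latency_s < 0) stop("risk_latency_s must be >= 0")
  activity <- if (time_outside_s > 0) {
    transitions / time_outside_s * 60
  } else if (transitions == 0) {
    NA_real_
  } else {
    stop("inconsistent record: transitions > 0 with time_outside_s = 0")
  }
  list(activity = activity, sheltering = sheltering_s,
       risk_taking = risk_latency_s)
}

#' State covariates: head-size PC, relative head size, condition, parasite
#' intensity
#'
#' Computes the individual-level state covariates: the first principal
#' component of the correlation-matrix PCA on the three head measures (sign
#' fixed so all loadings are positive), relative head size and body condition
#' as ordinary least-squares residuals of the head PC and body weight on
#' snout-vent length, and parasite infection intensity as the mean infected
#' cells per 1000 red blood cells over the three smear scans.
#'
#' @param covariates Tibble with columns `individual`, `svl_cm`, `bw_g`,
#'   `pileus_length_cm`, `pileus_width_cm`, `head_width_cm`,
#'   `parasite_count_1..3` (as written by [simulate_covariate_table()]; the
#'   same schema is accepted for real field data).
#' @return Tibble: `individual`, `svl`, `head_size_pc`, `relative_head_size`,
#'   `condition`, `parasite_intensity`; PCA loadings and variance share kept
#'   as attribute `"head_pca"`.
#' @export
prepare_covariates <- function(covariates) {
  need <- c("individual", "svl_cm", "bw_g", "pileus_length_cm",
            "pileus_width_cm", "head_width_cm", "parasite_count_1",
            "parasite_count_2", "parasite_count_3")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) stop("covariates missing columns: ",
                         paste(miss, collapse = ", "))
  cc <- covariates[complete.cases(covariates[need]), ]
  if (nrow(cc) < 3L) stop("need >= 3 individuals with complete measurements")

  hm <- as.matrix(cc[c("pileus_length_cm", "pileus_width_cm",
                       "head_width_cm")])
  if (any(apply(hm, 2, sd) == 0)) {
    stop("constant head-measure column; PCA on the correlation matrix is ",
         "undefined")
  }
  pca <- prcomp(hm, center = TRUE, scale. = TRUE)
  load1 <- pca$rotation[, 1]
  if (sum(load1) < 0) {           # fix sign: larger heads score higher
    load1 <- -load1
    pca$x[, 1] <- -pca$x[, 1]
  }
  head_pc <- pca$x[, 1]
  prop_var <- pca$sdev[1]^2 / sum(pca$sdev^2)

  rel_head <- unname(resid(lm(head_pc ~ cc$svl_cm)))
  condition <- unname(resid(lm(cc$bw_g ~ cc$svl_cm)))
  intensity <- rowMeans(cc[c("parasite_count_1", "parasite_count_2",
                             "parasite_count_3")])

  out <- tibble::tibble(
    individual = cc$individual, svl = cc$svl_cm,
    head_size_pc = unname(head_pc), relative_head_size = rel_head,
    condition = condition, parasite_intensity = unname(intensity)
  )
  attr(out, "head_pca") <- list(loadings = load1, prop_var = prop_var)
  out
}

#' Z-standardize trait and covariate columns
#'
#' Appends a `<col>_z` column for every requested column, centred to mean 0
#' and scaled to sample SD 1 over non-missing rows.  The transform constants
#' are stored in attribute `"scaling"` so fitted standardized intercepts can
#' be mapped back to natural units with [destandardize()].
#'
#' @param data Tibble.
#' @param cols Character vector of numeric columns to standardize.
#' @return `data` with the `_z` columns appended and attribute `"scaling"`.
#' @export
standardize_traits <- function(data, cols) {
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("columns not found: ", paste(miss, collapse = ", "))
  scaling <- attr(data, "scaling") %||% list()
  for (cl in cols) {
    x <- data[[cl]]
    m <- mean(x, na.rm = TRUE)
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("column '", cl, "' has zero variance; cannot standardize")
    }
    data[[paste0(cl, "_z")]] <- (x - m) / s
    scaling[[cl]] <- c(mean = m, sd = s)
  }
  attr(data, "scaling") <- scaling
  data
}

#' Back-transform a standardized value to natural units
#'
#' @param x Standardized value(s), e.g. a fitted intercept.
#' @param data A table carrying the `"scaling"` attribute written by
#'   [standardize_traits()], or that attribute itself.
#' @param col Name of the original column.
#' @return `x * sd + mean` on the column's natural scale.
#' @export
destandardize <- function(x, data, col) {
  scaling <- if (is.list(data) && is.null(attr(data, "scaling"))) {
    data
  } else {
    attr(data, "scaling")
  }
  if (is.null(scaling[[col]])) stop("no scaling recorded for column '",
                                    col, "'")
  x * scaling[[col]]["sd"] + scaling[[col]]["mean"]
}

#' Build the analysis trait table from raw observation logs
#'
#' Runs the full derivation: per individual-day thermal traits from the
#' temperature log, behavioural traits from the trial log, state covariates
#' from the measurement table, natural-log transformation of the sheltering
#' and risk-taking latencies (`log(x + 1)`, guarding zeros), and
#' z-standardization of all responses and continuous covariates.  Thermal and
#' behavioural assay days alternate in the design, so each occasion row
#' carries either the thermal or the behavioural trait block, never both.
#'
#' @param raw A `raw_dataset` (from [simulate_raw_dataset()] or read back
#'   from disk with the same schema).
#' @param censor_s Trial length at which risk-taking latencies are
#'   right-censored (default 3600 s); values at or above it are kept as-is
#'   and flagged in column `risk_censored`.
#' @return A long tibble, one row per individual x occasion, with natural and
#'   standardized (`_z`) trait and covariate columns, an `assay` column
#'   (`"thermal"`/`"behaviour"`), per-assay day index `day`, and the
#'   `"scaling"` attribute for back-transformation.
#' @export
derive_trait_table <- function(raw, censor_s = 3600) {
  stopifnot(is.list(raw),
            all(c("thermal_log", "behaviour_log", "covariates") %in%
                  names(raw)))

  th <- raw$thermal_log |>
    dplyr::group_by(.data$individual, .data$day) |>
    dplyr::summarise(
      t_sel = derive_thermal_traits(.data$body_temp_c)$t_sel,
      t_set = derive_thermal_traits(.data$body_temp_c)$t_set,
      t_vmax = derive_thermal_traits(.data$body_temp_c)$t_vmax,
      .groups = "drop"
    ) |>
    dplyr::mutate(assay = "thermal", occasion = 2L * .data$day - 1L)

  bl <- raw$behaviour_log
  bt <- mapply(derive_behaviour_traits, bl$sheltering_s, bl$transitions,
               bl$time_outside_s, bl$risk_latency_s, SIMPLIFY = FALSE)
  bh <- dplyr::mutate(
    bl[c("individual", "day")],
    activity = vapply(bt, `[[`, numeric(1), "activity"),
    sheltering = vapply(bt, `[[`, numeric(1), "sheltering"),
    risk_taking = vapply(bt, `[[`, numeric(1), "risk_taking"),
    risk_censored = .data$risk_taking >= censor_s,
    assay = "behaviour", occasion = 2L * .data$day
  )
  # log-transform the two latency-type traits (natural log of seconds + 1)
  bh$sheltering <- log1p(bh$sheltering)
  bh$risk_taking <- log1p(bh$risk_taking)

  tab <- dplyr::bind_rows(th, bh) |>
    dplyr::arrange(.data$individual, .data$occasion)

  cov <- prepare_covariates(raw$covariates)
  tab <- dplyr::left_join(tab, cov, by = "individual")

  # per-assay standardized day index (time covariate of the mean submodels);
  # computed before standardization so later plain-column assignments keep
  # the "scaling" attribute intact
  tab$time_z <- NA_real_
  for (a in unique(tab$assay)) {
    idx <- tab$assay == a
    tab$time_z[idx] <- .standardized_time(tab$day[idx])
  }

  tab <- standardize_traits(
    tab,
    cols = c("t_sel", "t_set", "t_vmax", "activity", "sheltering",
             "risk_taking", "svl", "relative_head_size", "condition",
             "parasite_intensity")
  )
  # analysis aliases used in the model design matrices
  tab$rel_head_z <- tab$relative_head_size_z
  tab$parasite_z <- tab$parasite_intensity_z
  tab$svl_parasite_z <- tab$svl_z * tab$parasite_z
  tab$rel_head_parasite_z <- tab$rel_head_z * tab$parasite_z
  tab$condition_parasite_z <- tab$condition_z * tab$parasite_z
  attr(tab, "head_pca") <- attr(cov, "head_pca")
  tab
}
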