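#' Bundled reference cohort tables
#'
#' Transcription of the printed per-patient tables of a published 20-patient
#' LAAO cohort (10 control, 10 device-related-thrombus): anatomy and device
#' configuration (`table1`), phase-resolved device-surface velocities
#' (`table2`, m/s), ECAP summaries (`table3`, 1/Pa) and the four binary risk
#' descriptors (`table4`), each for the implanted post-LAAO pose and, where
#' simulated, the proposed pulmonary-ridge-covering pose. Values are the
#' printed numbers only (including one obvious misprint in a `table3`
#' standard deviation, kept as printed); they make the cohort arithmetic
#' executable without patient data.
#'
#' @return list of four data.frames: `table1`, `table2`, `table3`, `table4`.
#' @export
laao_cohort_tables <- function() {
  rd <- function(f) {
    utils::read.csv(system.file("extdata", f, package = "laaoflow"),
                    stringsAsFactors = FALSE)
  }
  list(table1 = rd("cohort_table1.csv"),
       table2 = rd("cohort_table2.csv"),
       table3 = rd("cohort_table3.csv"),
       table4 = rd("cohort_table4.csv"))
}

#' Generate a synthetic cohort of configuration records
#'
#' Draws per-patient anatomy from normal distributions truncated at zero,
#' parameterized to mimic the reference cohort strata (left-atrial volume
#' 163.6 +/- 39 mL control vs 177.1 +/- 58 mL DRT; appendage volume
#' 12.75 +/- 4.6 vs 15.29 +/- 6.29 mL), together with ostium geometry
#' (perimeter derived from area with a shape factor respecting the
#' isoperimetric inequality), device type/size and a pulmonary-ridge
#' coverage flag. Deterministic per seed.
#'
#' @param n_control,n_drt stratum sizes (>= 0).
#' @param effect_spec named list overriding any of the distribution
#'   parameters `la_mean_control`, `la_sd_control`, `la_mean_drt`,
#'   `la_sd_drt`, `laa_mean_control`, `laa_sd_control`, `laa_mean_drt`,
#'   `laa_sd_drt`, `area_mean`, `area_sd`, `p_plug_control`, `p_plug_drt`,
#'   `p_covered`.
#' @param seed integer seed.
#' @return data.frame with one row per synthetic patient: `patient`,
#'   `outcome`, `device_type`, `device_size`, `la_volume`, `laa_volume`,
#'   `ostium_area`, `ostium_perimeter`, `pr_covered`.
#' @export
generate_cohort_fixture <- function(n_control, n_drt, effect_spec = list(),
                                    seed = 1L) {
  if (n_control < 0 || n_drt < 0) {
    stop("validation error: stratum sizes must be non-negative")
  }
  par <- utils::modifyList(list(
    la_mean_control = 163.6, la_sd_control = 39,
    la_mean_drt = 177.1, la_sd_drt = 58,
    laa_mean_control = 12.75, laa_sd_control = 4.6,
    laa_mean_drt = 15.29, laa_sd_drt = 6.29,
    area_mean = 630, area_sd = 230,
    p_plug_control = 0.6, p_plug_drt = 0.4,
    p_covered = 0.35), effect_spec)
  n <- n_control + n_drt
  if (n == 0L) {
    return(data.frame(patient = integer(), outcome = character(),
                      device_type = character(), device_size = numeric(),
                      la_volume = numeric(), laa_volume = numeric(),
                      ostium_area = numeric(), ostium_perimeter = numeric(),
                      pr_covered = logical()))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  rtnorm <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  outcome <- c(rep("control", n_control), rep("DRT", n_drt))
  la <- c(rtnorm(n_control, par$la_mean_control, par$la_sd_control),
          rtnorm(n_drt, par$la_mean_drt, par$la_sd_drt))
  laa <- c(rtnorm(n_control, par$laa_mean_control, par$laa_sd_control),
           rtnorm(n_drt, par$laa_mean_drt, par$laa_sd_drt))
  area <- rtnorm(n, par$area_mean, par$area_sd)
  shape <- 1 + abs(stats::rnorm(n, 0.06, 0.04))
  peri <- sqrt(4 * pi * area) * shape
  p_plug <- ifelse(outcome == "control", par$p_plug_control, par$p_plug_drt)
  dtype <- ifelse(stats::runif(n) < p_plug, "plug", "pacifier")
  d_mean <- 2 * sqrt(area / pi)  # equivalent-circle sizing diameter, mm
  dsize <- pmax(16, pmin(35, round(1.15 * d_mean)))
  covered <- stats::runif(n) < par$p_covered
  data.frame(patient = seq_len(n), outcome = outcome, device_type = dtype,
             device_size = dsize, la_volume = la, laa_volume = laa,
             ostium_area = area, ostium_perimeter = peri,
             pr_covered = covered, stringsAsFactors = FALSE)
}

#' Binary DRT risk descriptors per configuration
#'
#' Applies the four descriptor thresholds to configuration records: low
#' average velocity (full-cycle mean strictly below `velocity_ms`),
#' re-circulation (a logical column), high ECAP (maximum strictly above
#' `ecap_pa_inv`) and high platelet adhesion (strictly above
#' `adhesion_pct` percent).
#'
#' @param records data.frame with columns `cycle_mean` (m/s), `max_ecap`
#'   (1/Pa), `pct_attached` (%), `recirculation` (logical).
#' @param velocity_ms,ecap_pa_inv,adhesion_pct thresholds (0.2 m/s,
#'   0.5 1/Pa, 10 %).
#' @return data.frame of logicals `low_avg_velocity`, `recirculation`,
#'   `high_ecap`, `high_platelet_adhesion`, one row per record.
#' @export
build_risk_table <- function(records, velocity_ms = 0.2, ecap_pa_inv = 0.5,
                             adhesion_pct = 10) {
  need <- c("cycle_mean", "max_ecap", "pct_attached", "recirculation")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("missing metric column(s): ", paste(miss, collapse = ", "))
  }
  for (i in seq_len(nrow(records))) {
    bad <- need[vapply(need, function(nm) is.na(records[[nm]][i]), TRUE)]
    if (length(bad)) {
      stop("record ", i, " is missing metrics: ", paste(bad, collapse = ", "))
    }
  }
  data.frame(
    low_avg_velocity = records$cycle_mean < velocity_ms,
    recirculation = as.logical(records$recirculation),
    high_ecap = records$max_ecap > ecap_pa_inv,
    high_platelet_adhesion = records$pct_attached > adhesion_pct)
}

#' Grouped mean and standard deviation of a cohort metric
#'
#' Arithmetic mean and sample (n-1) standard deviation per group; missing
#' entries are excluded and counted. Empty groups are omitted with a
#' warning.
#'
#' @param records data.frame.
#' @param metric metric column name.
#' @param group_by grouping column name.
#' @return data.frame with `group`, `n`, `n_missing`, `mean`, `sd`
#'   (`sd` is `NA` for single-record groups).
#' @export
cohort_summary <- function(records, metric, group_by) {
  if (!metric %in% names(records)) stop("no column ", metric)
  if (!group_by %in% names(records)) stop("no column ", group_by)
  out <- do.call(rbind, lapply(split(records, records[[group_by]]),
                               function(g) {
    v <- g[[metric]]
    n_missing <- sum(is.na(v))
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NULL)
    data.frame(group = g[[group_by]][1], n = length(v),
               n_missing = n_missing, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
  }))
  if (is.null(out)) {
    warning("all groups empty")
    return(data.frame(group = character(), n = integer(),
                      n_missing = integer(), mean = numeric(),
                      sd = numeric()))
  }
  rownames(out) <- NULL
  out
}

#' Count records satisfying a predicate
#'
#' @param records data.frame.
#' @param predicate function taking the data.frame and returning a logical
#'   vector (`NA` counts as FALSE).
#' @return integer count.
#' @export
threshold_counts <- function(records, predicate) {
  v <- predicate(records)
  sum(v, na.rm = TRUE)
}

#' Descriptor-outcome concordance
#'
#' For DRT patients a descriptor agrees with the clinical outcome when it
#' is raised (TRUE); for controls when it is not. Reports the per-patient
#' agreement count (0-4) and the tallies of patients with complete (4/4)
#' and at-least-3/4 agreement. Order-invariant.
#'
#' @param risk_rows data.frame of four logical descriptor columns (one row
#'   per patient, post-LAAO configuration).
#' @param outcomes character vector, `"control"` or `"DRT"`, per patient.
#' @return list with `agreement` (integer per patient), `n_complete`,
#'   `n_at_least_3`.
#' @export
concordance <- function(risk_rows, outcomes) {
  if (nrow(risk_rows) != length(outcomes)) {
    stop("one outcome per risk row required")
  }
  if (any(is.na(outcomes))) {
    stop("missing outcome for patient(s): ",
         paste(which(is.na(outcomes)), collapse = ", "))
  }
  m <- as.matrix(risk_rows)
  storage.mode(m) <- "logical"
  want <- outcomes == "DRT"
  agree <- rowSums(m == want)
  list(agreement = as.integer(agree),
       n_complete = sum(agree == 4L),
       n_at_least_3 = sum(agree >= 3L))
}

#' Risk descriptors from the printed overview table
#'
#' Converts the YES/NO descriptor columns of the bundled `table4` for one
#' configuration into the logical layout of [build_risk_table()].
#'
#' @param table4 the `table4` data.frame of [laao_cohort_tables()].
#' @param config `"post"` or `"pr"`.
#' @return data.frame of logicals (`NA` rows dropped for absent
#'   configurations) with the patient and outcome columns retained.
#' @export
risk_table_from_printed <- function(table4, config = c("post", "pr")) {
  config <- match.arg(config)
  cols <- paste0(c("low_vel_", "recirc_", "ecap_", "adhesion_"), config)
  keep <- stats::complete.cases(table4[cols])
  out <- data.frame(
    patient = table4$patient[keep], outcome = table4$outcome[keep],
    low_avg_velocity = table4[[cols[1]]][keep] == "YES",
    recirculation = table4[[cols[2]]][keep] == "YES",
    high_ecap = table4[[cols[3]]][keep] == "YES",
    high_platelet_adhesion = table4[[cols[4]]][keep] == "YES")
  out
}

#' End-to-end synthetic device-configuration pipeline
#'
#' For each requested device configuration on one synthetic atrium: builds
#' and places the device, generates the pulsatile flow field and wall shear
#' stress, computes phase-resolved velocities, the recirculation score,
#' TAWSS/OSI/ECAP summaries, pulmonary-ridge coverage and the platelet
#' transport episode, then assembles the configuration record and its four
#' binary risk descriptors. All thresholds and seeds used are echoed in the
#' result.
#'
#' @param config a named list (or path to a JSON/YAML file) with optional
#'   elements `atrium` (arguments to [atrium_spec()]), `waveforms`
#'   (arguments to [waveform_set()]), `flow` (extra arguments to
#'   [generate_flow()]), `configurations` (list of lists with `name`,
#'   `device_type`, `size`, `disk_diameter`, `depth`), `thresholds`
#'   (`velocity_ms`, `ecap_pa_inv`, `adhesion_pct`, `pr_distance_mm`),
#'   `seed`, `n_sub`, `transport` (logical; skip the particle episode when
#'   FALSE).
#' @return an object of class `laao_report`: list with `records`
#'   (data.frame), `risk` (data.frame), `thresholds`, `seed`, and the
#'   per-configuration detail list `detail`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("yaml package needed to read YAML configs")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  thr <- utils::modifyList(list(velocity_ms = 0.2, ecap_pa_inv = 0.5,
                                adhesion_pct = 10, pr_distance_mm = 10),
                           config$thresholds %||% list())
  seed <- config$seed %||% 1L
  confs <- config$configurations %||% list()
  if (length(confs) == 0L) {
    warning("empty configuration list: empty report")
    return(structure(list(records = data.frame(), risk = data.frame(),
                          thresholds = thr, seed = seed, detail = list()),
                     class = "laao_report"))
  }
  spec <- do.call(atrium_spec, config$atrium %||% list())
  wf <- do.call(waveform_set, config$waveforms %||% list())
  mesh0 <- generate_atrium(spec)
  do_transport <- config$transport %||% TRUE

  detail <- list()
  rows <- list()
  for (cf in confs) {
    name <- cf$name %||% paste0("config_", length(detail) + 1L)
    dspec <- device_spec(cf$device_type %||% "plug",
                         size = cf$size %||% 24,
                         disk_diameter = cf$disk_diameter)
    device <- build_device(dspec)
    mesh <- mesh0
    attr(mesh, "device_depth") <- cf$depth %||% 0
    placed <- place_device(device, mesh, depth = cf$depth %||% 0)
    # the merged mesh only widens the sampling grid to cover any device
    # protrusion; the analytic field itself reads the atrium attributes
    series <- do.call(generate_flow,
                      c(list(mesh = merge_meshes(mesh, placed),
                             waveforms = wf, seed = seed),
                        config$flow %||% list()))
    region <- device_region(mesh, placed)
    vs_sys <- phase_average_speed(series, region, phase_window("systole"))
    vs_dia <- phase_average_speed(series, region, phase_window("diastole"))
    vs_cyc <- phase_average_speed(series, region, phase_window("full_cycle"))
    rec <- recirculation_index(series, region,
                               speed_limit = thr$velocity_ms)
    wall <- merge_meshes(mesh, placed)
    wss <- generate_wss(series, wall)
    em <- ecap(wss)
    esum <- index_summary(em, wss$areas)
    cov <- pr_coverage(mesh, placed, threshold_mm = thr$pr_distance_mm)
    pct <- NA_real_
    transport <- NULL
    if (isTRUE(do_transport)) {
      inl <- inlet_facets(mesh)
      plan <- plan_injection(vol_la = mesh_volume_ml(mesh),
                             n_inj = nrow(inl$centroids),
                             dt = wf$dt)
      transport <- run_transport(series, mesh, plan, seed = seed,
                                 device = placed,
                                 n_sub = config$n_sub %||% 10L)
      pct <- transport$pct_attached
    }
    rows[[name]] <- data.frame(
      config = name, device_type = dspec$device_type, device_size = dspec$size,
      depth_mm = cf$depth %||% 0, pr_covered = cov$covered,
      pr_distance_mm = cov$min_distance_to_device,
      sys_mean = vs_sys$mean, sys_sd = vs_sys$sd,
      dia_mean = vs_dia$mean, dia_sd = vs_dia$sd,
      cycle_mean = vs_cyc$mean, cycle_sd = vs_cyc$sd,
      recirc_score = rec$score, recirculation = rec$flag,
      max_ecap = esum$max, mean_ecap = esum$mean, sd_ecap = esum$sd,
      pct_attached = pct, stringsAsFactors = FALSE)
    detail[[name]] <- list(coverage = cov, region = region,
                           velocity = list(systole = vs_sys,
                                           diastole = vs_dia,
                                           full_cycle = vs_cyc),
                           recirculation = rec, ecap_summary = esum,
                           transport = transport)
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  risk <- if (all(!is.na(records$pct_attached))) {
    build_risk_table(records, thr$velocity_ms, thr$ecap_pa_inv,
                     thr$adhesion_pct)
  } else {
    rr <- records
    rr$pct_attached <- ifelse(is.na(rr$pct_attached), 0, rr$pct_attached)
    build_risk_table(rr, thr$velocity_ms, thr$ecap_pa_inv, thr$adhesion_pct)
  }
  structure(list(records = records, risk = risk, thresholds = thr,
                 seed = seed, detail = detail),
            class = "laao_report")
}

# chamber volume of a generated atrium in mL (1 mL = 1000 mm^3)
mesh_volume_ml <- function(mesh) {
  semi <- attr(mesh, "chamber_semi_axes")
  if (!is.null(semi)) {
    (4 / 3) * pi * prod(semi) / 1000
  } else {
    mesh_volume(mesh) / 1000
  }
}

#' @export
print.laao_report <- function(x, ...) {
  cat("laao_report:", nrow(x$records), "configuration(s)\n")
  if (nrow(x$records)) {
    print(x$records[, c("config", "device_type", "depth_mm", "pr_covered",
                        "cycle_mean", "max_ecap", "pct_attached")])
  }
  invisible(x)
}
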