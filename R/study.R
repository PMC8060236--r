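#' Run a full synthetic study from one configuration
#'
#' Orchestrates the pipeline end to end: builds the configured branched
#' phantoms, measures each bridging stent (centerline, take-off angle,
#' shape-index profile, zone metrics, shortening), simulates the
#' configured cohort, and writes per-vessel metrics plus pre-/post-
#' operative group-summary tables as CSV.  All stages run before anything
#' is written, so an invalid configuration fails with a stage-tagged
#' error and leaves no partial tables.  Deterministic for a fixed
#' configuration and seed.
#'
#' @param config a list, or path to a YAML file with the same structure;
#'   see `system.file("extdata", "demo_study.yaml", package =
#'   "stentgeom")` for the bundled demo.  Fields: `seed`, `spacing_mm`
#'   (voxel), `section_spacing_mm`, `si_definition`, `out_dir`,
#'   `phantoms` (list: `name`, `parent` = list(length, radius), `branch`
#'   = list(takeoff_angle_deg, origin_arclength, length, radius, si,
#'   cuff_end_arclength, vessel_origin_arclength, nominal_stent_length)),
#'   and `cohort` (list: `n_per_cell` or `reference_cells: yes`, `seed`).
#' @return (invisibly) list with `vessel_metrics`, `cohort`,
#'   `summary_stent`, `summary_vessel`, `preop_vessel`, `log`, and the
#'   paths written.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg_get <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  seed <- as.integer(cfg_get("seed", 1L))
  spacing <- cfg_get("spacing_mm", 0.5)
  sec_sp <- cfg_get("section_spacing_mm", 1)
  si_def <- cfg_get("si_definition", "feret")
  out_dir <- cfg_get("out_dir", ".")
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  # stage 1: validate phantom configs before any heavy work
  phantoms <- cfg_get("phantoms", list())
  for (ph in phantoms) {
    b <- ph$branch
    if (is.null(b)) next
    ce <- b$cuff_end_arclength
    vo <- b$vessel_origin_arclength
    if (!is.null(ce) && !is.null(vo) &&
        !(0 < ce && ce < vo && vo < b$length)) {
      stop("config stage: phantom '", ph$name,
           "': landmarks out of order (need 0 < cuff_end < vessel_origin < length)")
    }
  }

  # stage 2: build and measure phantoms
  vessel_rows <- list()
  for (ph in phantoms) {
    name <- if (!is.null(ph$name)) ph$name else "phantom"
    pcfg <- ph$parent
    bcfg <- ph$branch
    parent <- phantom_straight(length = pcfg$length, radius = pcfg$radius)
    res <- tryCatch({
      bs <- branch_spec(
        origin_arclength = bcfg$origin_arclength,
        takeoff_angle_deg = bcfg$takeoff_angle_deg,
        length = bcfg$length,
        radius = if (!is.null(bcfg$radius)) bcfg$radius else 3,
        si = if (!is.null(bcfg$si)) bcfg$si else 1,
        cuff_end_arclength = bcfg$cuff_end_arclength,
        vessel_origin_arclength = bcfg$vessel_origin_arclength,
        nominal_stent_length = bcfg$nominal_stent_length)
      phb <- make_branched_phantom(parent, list(bs))
      tr <- phb$branch_truths[[1]]
      ptr <- phb$parent_truth
      measure_branch(
        phb$mesh, branch_label = 1L,
        parent_ends = rbind(ptr$centerline$points[1, ],
                            ptr$centerline$points[nrow(ptr$centerline$points), ]),
        branch_ends = rbind(tr$centerline$points[1, ],
                            tr$centerline$points[nrow(tr$centerline$points), ]),
        cuff_end_s = bcfg$cuff_end_arclength,
        vessel_origin_s = bcfg$vessel_origin_arclength,
        nominal_length = bcfg$nominal_stent_length,
        spacing_mm = spacing, section_spacing_mm = sec_sp,
        si_definition = si_def)
    }, error = function(e) {
      stop("measurement stage: phantom '", name, "': ", conditionMessage(e))
    })
    note("phantom '%s': %d sections, %d failed", name,
         nrow(res$profile), attr(res$profile, "n_failed"))
    row <- as.data.frame(res$metrics)
    row$toa_deg <- res$toa$angle_deg
    row <- cbind(data.frame(vessel_id = name), row)
    vessel_rows[[length(vessel_rows) + 1L]] <- row
  }
  vessel_metrics <- if (length(vessel_rows)) do.call(rbind, vessel_rows)

  # stage 3: cohort simulation and statistics
  ccfg <- cfg_get("cohort", NULL)
  cohort <- summary_stent <- summary_vessel <- preop_vessel <- NULL
  if (!is.null(ccfg)) {
    cells <- if (isTRUE(ccfg$reference_cells)) beva_cohort_cells() else NULL
    cspec <- cohort_spec(cells = cells,
                         n_per_cell = if (!is.null(ccfg$n_per_cell))
                           ccfg$n_per_cell else 3,
                         seed = if (!is.null(ccfg$seed)) ccfg$seed else seed)
    cohort <- simulate_cohort(cspec)
    summary_stent <- cohort_summary_table(cohort, group_by = "stent_type")
    summary_vessel <- cohort_summary_table(
      cohort,
      metrics = c("toa_post_deg", "zone1_length", "zone1_si",
                  "zone2_length", "zone2_si", "zone3_length", "zone3_si",
                  "nominal_length", "total_length", "shortening_pct"),
      group_by = "vessel_type")
    preop_vessel <- cohort_summary_table(
      cohort,
      metrics = c("target_vessel_diameter", "nominal_stent_diameter",
                  "toa_pre_deg", "aneurysm_diameter", "lumen_diameter"),
      group_by = "vessel_type")
    note("cohort: %d vessels simulated (seed %d)", nrow(cohort),
         cspec$seed)
  }

  # stage 4: write everything
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, fname) {
    p <- file.path(out_dir, fname)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(vessel_metrics)) wr(vessel_metrics, "vessel_metrics.csv")
  if (!is.null(cohort)) {
    wr(as.data.frame(cohort), "cohort.csv")
    wr(summary_stent, "summary_by_stent.csv")
    wr(summary_vessel, "summary_by_vessel.csv")
    wr(preop_vessel, "preop_by_vessel.csv")
  }
  writeLines(log_lines, file.path(out_dir, "study_log.txt"))
  paths <- c(paths, file.path(out_dir, "study_log.txt"))
  invisible(list(vessel_metrics = vessel_metrics, cohort = cohort,
                 summary_stent = summary_stent,
                 summary_vessel = summary_vessel,
                 preop_vessel = preop_vessel,
                 log = log_lines, paths = paths))
}
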