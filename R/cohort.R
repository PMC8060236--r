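#' Specification of a synthetic B-EVAR cohort
#'
#' Describes the factorial structure (target vessels x bridging-stent
#' types) and the per-metric Gaussian effect model from which synthetic
#' per-vessel records are drawn.  Metrics are sampled from truncated
#' Gaussians so shape indices stay in (0, 1], angles in [0, 180] and
#' lengths positive.
#'
#' @param cells data.frame with columns `vessel_type`, `stent_type`, `n`
#'   (records per cell); or NULL to build from `n_per_cell`.
#' @param n_per_cell count used for every vessel x stent cell when
#'   `cells` is NULL.
#' @param vessel_types,stent_types factor vocabularies.
#' @param effect_model named list; each element describes one metric as
#'   `list(by = "stent_type"|"vessel_type"|"none", mean = named vector,
#'   sd = named vector, range = c(lo, hi))`.
#' @param seed integer RNG seed used by [simulate_cohort()].
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(cells = NULL, n_per_cell = 3,
                        vessel_types = c("CTR", "SMA", "LRA", "RRA"),
                        stent_types = c("Fluency", "Covera", "VBX"),
                        effect_model = beva_effect_model(),
                        seed = 1L) {
  if (is.null(cells)) {
    cells <- expand.grid(vessel_type = vessel_types,
                         stent_type = stent_types,
                         stringsAsFactors = FALSE)
    cells$n <- n_per_cell
  }
  stopifnot(all(c("vessel_type", "stent_type", "n") %in% names(cells)))
  if (any(cells$n < 1)) stop("empty cells are not allowed")
  if (!all(cells$vessel_type %in% vessel_types) ||
      !all(cells$stent_type %in% stent_types)) {
    stop("cell labels outside the declared vocabularies")
  }
  for (m in names(effect_model)) {
    em <- effect_model[[m]]
    if (any(em$sd < 0)) stop("negative SD for metric ", m)
  }
  structure(list(cells = cells, vessel_types = vessel_types,
                 stent_types = stent_types, effect_model = effect_model,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default effect model of a post-B-EVAR cohort
#'
#' Group means and standard deviations for each geometric metric,
#' patterned on a clinical B-EVAR series: renal arteries take off more
#' acutely than the celiac trunk and SMA; the balloon-expandable stent
#' (VBX) holds higher shape index in zones 2-3 but shortens most; zone-1
#' geometry is dictated by the main-body cuff and is common to all
#' stents.
#'
#' @return named list usable as `effect_model` in [cohort_spec()].
#' @export
beva_effect_model <- function() {
  st <- c("Fluency", "Covera", "VBX")
  vt <- c("CTR", "SMA", "LRA", "RRA")
  sv <- function(x, lv) stats::setNames(x, lv)
  list(
    toa_pre_deg = list(by = "vessel_type",
                       mean = sv(c(117.5, 115.8, 104.5, 97.3), vt),
                       sd = sv(c(28.4, 28.0, 28.9, 29.6), vt),
                       range = c(0, 180)),
    toa_post_deg = list(by = "stent_type",
                        mean = sv(c(156.75, 158.2, 140.6), st),
                        sd = sv(c(13.74, 11.7, 26.2), st),
                        range = c(0, 180)),
    target_vessel_diameter = list(by = "vessel_type",
                                  mean = sv(c(8.1, 7.8, 6.1, 5.9), vt),
                                  sd = sv(c(0.6, 1.1, 1.1, 1.1), vt),
                                  range = c(1, Inf)),
    nominal_stent_diameter = list(by = "vessel_type",
                                  mean = sv(c(8.5, 8.7, 6.4, 6.4), vt),
                                  sd = sv(c(0.9, 0.7, 0.7, 0.7), vt),
                                  range = c(1, Inf)),
    aneurysm_diameter = list(by = "vessel_type",
                             mean = sv(c(50.9, 45.8, 34.7, 35.5), vt),
                             sd = sv(c(10.2, 13.9, 5.9, 6.4), vt),
                             range = c(5, Inf)),
    lumen_diameter = list(by = "vessel_type",
                          mean = sv(c(36.4, 34.3, 27.3, 28.5), vt),
                          sd = sv(c(6.1, 6.9, 2.5, 2.3), vt),
                          range = c(5, Inf)),
    zone1_length = list(by = "stent_type",
                        mean = sv(c(17.71, 18.19, 18.37), st),
                        sd = sv(c(0.63, 0.92, 1.02), st),
                        range = c(1, Inf)),
    zone2_length = list(by = "stent_type",
                        mean = sv(c(27.7, 32.33, 32.0), st),
                        sd = sv(c(8.6, 12.4, 9.0), st),
                        range = c(1, Inf)),
    zone3_length = list(by = "stent_type",
                        mean = sv(c(23.5, 22.58, 19.25), st),
                        sd = sv(c(7.26, 11.4, 11.3), st),
                        range = c(1, Inf)),
    zone1_si = list(by = "stent_type",
                    mean = sv(c(0.88, 0.87, 0.91), st),
                    sd = sv(c(0.03, 0.04, 0.03), st),
                    range = c(0.01, 1)),
    zone2_si = list(by = "stent_type",
                    mean = sv(c(0.81, 0.89, 0.92), st),
                    sd = sv(c(0.06, 0.03, 0.02), st),
                    range = c(0.01, 1)),
    zone3_si = list(by = "stent_type",
                    mean = sv(c(0.81, 0.88, 0.93), st),
                    sd = sv(c(0.05, 0.05, 0.02), st),
                    range = c(0.01, 1)),
    nominal_length = list(by = "stent_type",
                          mean = sv(c(66.67, 72.73, 70.64), st),
                          sd = sv(c(10.0, 13.5, 10.5), st),
                          range = c(10, Inf)),
    shortening_pct = list(by = "stent_type",
                          mean = sv(c(4.86, 2.23, 11.12), st),
                          sd = sv(c(4.63, 2.18, 5.65), st),
                          range = c(-50, 90))
  )
}

#' Cell counts of the reference clinical cohort
#'
#' The vessel x stent allocation of the 38 treated branches (11 CTR, 11
#' SMA, 8 LRA, 8 RRA bridged with 10 Fluency, 12 Covera, 16 VBX stents).
#' @return data.frame with `vessel_type`, `stent_type`, `n`.
#' @export
beva_cohort_cells <- function() {
  data.frame(
    vessel_type = rep(c("CTR", "SMA", "LRA", "RRA"), times = 3),
    stent_type = rep(c("Fluency", "Covera", "VBX"), each = 4),
    n = c(3, 3, 2, 2,
          2, 4, 3, 3,
          6, 4, 3, 3))
}

#' Simulate a synthetic cohort of per-vessel stent metrics
#'
#' One record per synthetic vessel, metrics drawn independently from the
#' truncated-Gaussian effect model of the spec.  Total measured stent
#' length is derived from nominal length and shortening so the three
#' length columns are mutually consistent.  Bit-reproducible for a fixed
#' seed; the caller's RNG state is left untouched.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of class `cohort_table`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  cells <- spec$cells
  n_tot <- sum(cells$n)
  tab <- data.frame(
    vessel_id = sprintf("V%03d", seq_len(n_tot)),
    vessel_type = rep(cells$vessel_type, times = cells$n),
    stent_type = rep(cells$stent_type, times = cells$n),
    stringsAsFactors = FALSE)
  for (m in names(spec$effect_model)) {
    em <- spec$effect_model[[m]]
    key <- switch(em$by, stent_type = tab$stent_type,
                  vessel_type = tab$vessel_type,
                  none = rep("all", n_tot))
    mu <- unname(em$mean[key])
    sdv <- unname(em$sd[key])
    tab[[m]] <- rtruncnorm(n_tot, mu, sdv, em$range[1], em$range[2])
  }
  if (all(c("nominal_length", "shortening_pct") %in% names(tab))) {
    tab$total_length <- tab$nominal_length * (1 - tab$shortening_pct / 100)
  }
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

# Truncated-normal sampling by vectorized rejection; exact for sd = 0
# (degenerate at the mean, clamped into range).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  tries <- 0L
  while (length(bad) > 0L && tries < 1000L) {
    out[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[out[bad] < lo | out[bad] > hi]
    tries <- tries + 1L
  }
  if (length(bad) > 0L) out[bad] <- pmin(pmax(mean[bad], lo), hi)
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d vessels (%s x %s)\n", nrow(x),
              paste(levels(factor(x$vessel_type)), collapse = "/"),
              paste(levels(factor(x$stent_type)), collapse = "/")))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Build the post-operative summary table (metric x stent type)
#'
#' Mean +/- SD per stent group with the omnibus p per metric, mirroring
#' the layout of a clinical post-operative geometrical evaluation table.
#'
#' @param table a `cohort_table`.
#' @param metrics metric columns to summarize.
#' @param group_by grouping column (default stent type).
#' @return data.frame, one row per metric.
#' @export
cohort_summary_table <- function(table,
                                 metrics = c("toa_post_deg", "zone1_length",
                                             "zone1_si", "zone2_length",
                                             "zone2_si", "zone3_length",
                                             "zone3_si", "nominal_length",
                                             "total_length",
                                             "shortening_pct"),
                                 group_by = "stent_type") {
  metrics <- intersect(metrics, names(table))
  rows <- lapply(metrics, function(m) {
    sg <- summarize_groups(table, m, group_by)
    cells <- stats::setNames(
      sprintf("%.2f +/- %.2f", sg$mean, sg$sd), sg$group)
    tot <- sprintf("%.2f +/- %.2f", mean(table[[m]], na.rm = TRUE),
                   stats::sd(table[[m]], na.rm = TRUE))
    out <- data.frame(metric = m, Total = tot, t(cells),
                      p_value = signif(attr(sg, "p_value"), 3),
                      stars = attr(sg, "stars"),
                      check.names = FALSE, stringsAsFactors = FALSE)
    out
  })
  do.call(rbind, rows)
}
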