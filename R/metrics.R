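#' Target-vessel take-off angle (TOA)
#'
#' Angle between the parent (aortic) centerline tangent at the branch
#' origin, oriented cranially (toward the parent's first point), and the
#' mean take-off direction of the branch over its first `window_mm` of
#' arclength.  Reported in degrees on the 0-180 scale: 0 is the most
#' acute take-off (branch recurving cranially), 180 a straight, caudally
#' parallel branch.
#'
#' @param parent parent [centerline_curve()], ordered cranial to caudal.
#' @param branch branch [centerline_curve()], first point proximal.
#' @param window_mm branch arclength over which the take-off direction is
#'   averaged (default 5 mm); shrunk with a warning when the branch is
#'   shorter.
#' @param gate_mm junction gate passed to [locate_branch_origin()].
#' @return list of class `toa_measurement`: `angle_deg`,
#'   `s_origin_parent`, `window_mm`.
#' @export
take_off_angle <- function(parent, branch, window_mm = 5, gate_mm = 10) {
  j <- locate_branch_origin(parent, branch, gate_mm = gate_mm)
  bl <- curve_length(branch)
  if (window_mm > bl) {
    warning(sprintf("branch (%.1f mm) shorter than window (%g mm); window shrunk",
                    bl, window_mm))
    window_mm <- bl
  }
  cranial <- -as.vector(tangent_at(parent, j$s_parent))
  # mean take-off direction = chord over the first window of arclength
  b0 <- branch$points[1, ]
  bw <- as.vector(point_at(branch, window_mm))
  dir <- bw - b0
  if (sqrt(sum(dir^2)) < 1e-9) stop("degenerate branch window")
  ang <- angle_between_deg(cranial, dir)
  structure(list(angle_deg = min(max(ang, 0), 180),
                 s_origin_parent = j$s_parent,
                 origin_point = j$origin_point,
                 window_mm = window_mm),
            class = "toa_measurement")
}

#' @export
print.toa_measurement <- function(x, ...) {
  cat(sprintf("take-off angle: %.1f deg (origin at parent s = %.1f mm, window %g mm)\n",
              x$angle_deg, x$s_origin_parent, x$window_mm))
  invisible(x)
}

#' Partition a stent centerline into the three bridging-stent zones
#'
#' Zone 1 runs from the stent origin to the end of the main-body branch
#' cuff, zone 2 from the cuff end to the native target-vessel origin
#' (across the aneurysm sac), zone 3 from the vessel origin to the stent
#' end.  Intervals are half-open, `[0, cuff_end)`, `[cuff_end,
#' vessel_origin)`, `[vessel_origin, total]`, so they partition the stent
#' exactly with boundary sections assigned downstream.
#'
#' @param stent_curve the stent [centerline_curve()].
#' @param cuff_end_s,vessel_origin_s landmark arclengths (mm), with
#'   `0 < cuff_end_s < vessel_origin_s < total length`.
#' @return list of class `zone_partition`: `cuff_end_s`,
#'   `vessel_origin_s`, `total_length`, `breaks` and `zone_lengths`.
#' @export
partition_zones <- function(stent_curve, cuff_end_s, vessel_origin_s) {
  L <- curve_length(stent_curve)
  if (!(0 < cuff_end_s && cuff_end_s < vessel_origin_s &&
        vessel_origin_s < L)) {
    stop(sprintf(
      "invalid landmarks: need 0 < cuff_end_s (%.2f) < vessel_origin_s (%.2f) < length (%.2f)",
      cuff_end_s, vessel_origin_s, L))
  }
  structure(list(cuff_end_s = cuff_end_s, vessel_origin_s = vessel_origin_s,
                 total_length = L,
                 breaks = c(0, cuff_end_s, vessel_origin_s, L),
                 zone_lengths = c(cuff_end_s, vessel_origin_s - cuff_end_s,
                                  L - vessel_origin_s)),
            class = "zone_partition")
}

#' @export
print.zone_partition <- function(x, ...) {
  cat(sprintf("zone_partition: L1 %.2f | L2 %.2f | L3 %.2f mm (total %.2f)\n",
              x$zone_lengths[1], x$zone_lengths[2], x$zone_lengths[3],
              x$total_length))
  invisible(x)
}

#' Longitudinal stent shortening
#'
#' Percentage difference between the nominal (labeled) stent length and
#' the actual length measured along the post-operative centerline:
#' `100 * (nominal - measured) / nominal`.  Positive values mean the
#' deployed stent is shorter than its label; negative values (measured
#' longer than nominal) are reported as-is.
#'
#' @param nominal_length,measured_length lengths in mm, both positive.
#' @export
stent_shortening <- function(nominal_length, measured_length) {
  if (nominal_length <= 0 || measured_length <= 0) {
    stop("lengths must be positive")
  }
  100 * (nominal_length - measured_length) / nominal_length
}

#' Total length and overlap of a multi-stent construct
#'
#' For vessels bridged with more than one (partially overlapping) stent,
#' the construct length is measured over the union of the per-stent
#' arclength intervals along the vessel centerline, counting overlap
#' once; the overlap length is reported separately and shortening against
#' a single nominal length is not defined.
#'
#' @param intervals numeric matrix or data.frame with two columns (start
#'   and end arclength, mm) per stent.
#' @return list with `total_length` (union), `overlap_length` (summed
#'   pairwise-covered length) and `n_stents`.
#' @export
multi_stent_length <- function(intervals) {
  iv <- as.matrix(intervals)
  if (ncol(iv) != 2L || any(iv[, 2] <= iv[, 1])) {
    stop("intervals must be (start, end) with end > start")
  }
  brk <- sort(unique(as.vector(iv)))
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  widths <- diff(brk)
  cover <- vapply(mids, function(m) sum(iv[, 1] <= m & m < iv[, 2]),
                  numeric(1))
  list(total_length = sum(widths[cover >= 1]),
       overlap_length = sum(widths[cover >= 2]),
       n_stents = nrow(iv))
}

#' Per-zone and whole-stent metrics
#'
#' Aggregates a cross-section shape-index profile over a zone partition:
#' per-zone centerline length, per-zone arithmetic mean SI, whole-stent
#' length and mean SI, and (single-stent implantations only) the
#' longitudinal shortening against nominal length.
#'
#' @param partition a [partition_zones()] result.
#' @param profile an [si_profile()] (sections ordered by arclength).
#' @param nominal_length nominal stent length, mm (NA when unknown).
#' @param single_stent logical; shortening is only defined for single
#'   stents (the multi-stent total is measured over the overlapping union,
#'   so nominal comparison is meaningless).
#' @return list of class `stent_metrics`.
#' @export
zone_metrics <- function(partition, profile, nominal_length = NA_real_,
                         single_stent = TRUE) {
  stopifnot(inherits(partition, "zone_partition"))
  br <- partition$breaks
  zone_of <- findInterval(profile$s, br[2:3]) + 1L  # half-open downstream
  counts <- tabulate(zone_of, nbins = 3L)
  if (any(counts == 0L)) {
    stop("zone ", which(counts == 0L)[1],
         " contains no sections; use a finer section spacing")
  }
  zmean <- vapply(1:3, function(z) mean(profile$si[zone_of == z]),
                  numeric(1))
  short <- if (single_stent && !is.na(nominal_length)) {
    stent_shortening(nominal_length, partition$total_length)
  } else NA_real_
  structure(list(zone_lengths = partition$zone_lengths,
                 zone_mean_si = zmean,
                 zone_n_sections = counts,
                 total_length = partition$total_length,
                 whole_mean_si = mean(profile$si),
                 nominal_length = nominal_length,
                 shortening_pct = short,
                 single_stent = single_stent),
            class = "stent_metrics")
}

#' @export
print.stent_metrics <- function(x, ...) {
  cat("stent_metrics\n")
  cat(sprintf("  length: %.2f mm total (zones %.2f / %.2f / %.2f)\n",
              x$total_length, x$zone_lengths[1], x$zone_lengths[2],
              x$zone_lengths[3]))
  cat(sprintf("  mean SI: %.3f whole (zones %.3f / %.3f / %.3f)\n",
              x$whole_mean_si, x$zone_mean_si[1], x$zone_mean_si[2],
              x$zone_mean_si[3]))
  if (!is.na(x$shortening_pct)) {
    cat(sprintf("  shortening: %.2f%% of nominal %.1f mm\n",
                x$shortening_pct, x$nominal_length))
  } else if (!x$single_stent) {
    cat("  shortening: suppressed (multi-stent vessel)\n")
  }
  invisible(x)
}

#' Flatten stent metrics to a one-row data frame
#' @param x a `stent_metrics`.
#' @param ... unused.
#' @export
as.data.frame.stent_metrics <- function(x, ...) {
  data.frame(toa_deg = NA_real_,
             zone1_length = x$zone_lengths[1],
             zone2_length = x$zone_lengths[2],
             zone3_length = x$zone_lengths[3],
             zone1_si = x$zone_mean_si[1],
             zone2_si = x$zone_mean_si[2],
             zone3_si = x$zone_mean_si[3],
             total_length = x$total_length,
             whole_si = x$whole_mean_si,
             nominal_length = x$nominal_length,
             shortening_pct = x$shortening_pct)
}

#' Measure a bridging stent end-to-end on a labelled phantom mesh
#'
#' Convenience pipeline used by the study driver and the validation
#' suite: voxelize the parent and branch components, extract both
#' centerlines, compute the take-off angle, slice the branch mesh into a
#' shape-index profile, partition into zones at the given landmarks and
#' aggregate.
#'
#' @param mesh labelled [surface_mesh()] from [make_branched_phantom()].
#' @param branch_label component label of the branch to measure.
#' @param parent_ends,branch_ends 2 x 3 matrices: source and target world
#'   points for centerline extraction of parent and branch.
#' @param cuff_end_s,vessel_origin_s zone landmarks (mm along the branch).
#' @param nominal_length nominal stent length, mm.
#' @param spacing_mm voxel spacing for centerline extraction.
#' @param section_spacing_mm cross-section spacing.
#' @param si_definition `"feret"` or `"chord"`.
#' @param single_stent passed to [zone_metrics()].
#' @return list with `toa` (a `toa_measurement`), `metrics`
#'   (`stent_metrics`), `profile` (`si_profile`), `parent_centerline`,
#'   `branch_centerline`.
#' @export
measure_branch <- function(mesh, branch_label, parent_ends, branch_ends,
                           cuff_end_s, vessel_origin_s,
                           nominal_length = NA_real_, spacing_mm = 0.5,
                           section_spacing_mm = 1,
                           si_definition = c("feret", "chord"),
                           single_stent = TRUE) {
  si_definition <- match.arg(si_definition)
  pmesh <- mesh_component(mesh, 0L)
  bmesh <- mesh_component(mesh, branch_label)
  pmap <- voxelize(pmesh, spacing_mm)
  bmap <- voxelize(bmesh, spacing_mm)
  pcl <- extract_centerline(pmap, parent_ends[1, ], parent_ends[2, ])
  bcl <- extract_centerline(bmap, branch_ends[1, ], branch_ends[2, ])
  toa <- take_off_angle(pcl, bcl)
  prof <- si_profile(bmesh, bcl, spacing_mm = section_spacing_mm,
                     definition = si_definition)
  part <- partition_zones(bcl, cuff_end_s, vessel_origin_s)
  metrics <- zone_metrics(part, prof, nominal_length = nominal_length,
                          single_stent = single_stent)
  list(toa = toa, metrics = metrics, profile = prof,
       parent_centerline = pcl, branch_centerline = bcl)
}
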