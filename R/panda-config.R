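#' Panda habitat camera configuration
#'
#' Per-camera scene geometry: useful-information polygon, panda and
#' technician entry/exit gates, visible (observable) zones with their
#' type, the zone-correspondence map toward the other cameras, and the
#' velocity weight (pixels of this view per world unit) used to make
#' speeds comparable across views.
#'
#' @param camera_id camera number (the study used 5-8).
#' @param resolution `c(w, h)` in pixels.
#' @param info_polygon useful-information [region_polygon()].
#' @param panda_gates list of half-open rectangles (`c(x, y, w, h)`).
#' @param technician_gate rectangle or `NULL`.
#' @param visible_zones named list of [region_polygon()]s.
#' @param zone_types named character vector, one of `"full"`, `"door"`,
#'   `"housing"`, `"basin"` per zone.
#' @param zone_correspondence named list: for each zone, a data.frame
#'   with columns `camera_id`, `zone` of the corresponding areas on the
#'   other cameras.
#' @param general_view logical; TRUE for the whole-arena views.
#' @param basin_zone rectangle of the bathing basin (camera 8) or `NULL`.
#' @param velocity_weight factor converting this camera's pixel
#'   displacements to the common (world) scale.
#' @param technician_height_frac movement-rectangle height fraction of the
#'   frame height characteristic of the standing technician.
#' @param world_affine optional 2x3 matrix mapping world `(x, y, 1)` to
#'   this camera's pixels; used by the compaction filter to transfer
#'   coordinates between views when a per-camera track is unavailable.
#' @return object of class `camera_config`.
#' @export
camera_config <- function(camera_id, resolution, info_polygon,
                          panda_gates = list(), technician_gate = NULL,
                          visible_zones = list(), zone_types = character(0),
                          zone_correspondence = list(),
                          general_view = FALSE, basin_zone = NULL,
                          velocity_weight = 1,
                          technician_height_frac = 0.6,
                          world_affine = NULL) {
  stopifnot(length(resolution) == 2L, velocity_weight > 0)
  if (length(visible_zones) && is.null(names(visible_zones)))
    stop("visible_zones must be named")
  structure(list(camera_id = camera_id, resolution = resolution,
                 info_polygon = info_polygon, panda_gates = panda_gates,
                 technician_gate = technician_gate,
                 visible_zones = visible_zones, zone_types = zone_types,
                 zone_correspondence = zone_correspondence,
                 general_view = general_view, basin_zone = basin_zone,
                 velocity_weight = velocity_weight,
                 technician_height_frac = technician_height_frac,
                 world_affine = world_affine),
            class = "camera_config")
}

#' Movement-strength thresholds
#'
#' The three feature-count bands that drive the per-camera state machine.
#'
#' @param low,mid,high feature counts, `low < mid < high`; `mid` is the
#'   movement threshold, `high` the session-(re)initialization/technician
#'   threshold.
#' @return object of class `motion_thresholds`.
#' @export
motion_thresholds <- function(low, mid, high) {
  if (!(low < mid && mid < high))
    stop("motion thresholds must satisfy low < mid < high")
  structure(list(low = low, mid = mid, high = high),
            class = "motion_thresholds")
}

#' Velocity thresholds for stress classification
#'
#' @param thr_v1,thr_v2,thr_v3 weighted velocities (common-scale pixels
#'   per frame), `thr_v1 > thr_v2 > thr_v3`.
#' @return object of class `velocity_thresholds`.
#' @export
velocity_thresholds <- function(thr_v1, thr_v2, thr_v3) {
  if (!(thr_v1 > thr_v2 && thr_v2 > thr_v3))
    stop("velocity thresholds must satisfy thr_v1 > thr_v2 > thr_v3")
  structure(list(thr_v1 = thr_v1, thr_v2 = thr_v2, thr_v3 = thr_v3),
            class = "velocity_thresholds")
}

# name of the first visible zone containing point p, else NA
zone_of_point <- function(p, cfg) {
  for (nm in names(cfg$visible_zones))
    if (point_in_polygon(p, cfg$visible_zones[[nm]])) return(nm)
  NA_character_
}

zone_type <- function(zone, cfg) {
  if (is.na(zone) || !zone %in% names(cfg$zone_types)) return(NA_character_)
  unname(cfg$zone_types[[zone]])
}

point_in_any_rect <- function(p, rects) {
  for (r in rects) if (point_in_rect(p, r)) return(TRUE)
  FALSE
}
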