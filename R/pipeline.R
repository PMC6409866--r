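# End-to-end orchestration: detect nuclei across fields, find landmarks and
# orient, build the population consensus and template mesh, binarise and
# warp every nucleus's signal channels, and composite per probe. The CLI
# subcommands are thin wrappers over these functions.

#' Detect, landmark and orient all nuclei in a set of fields
#'
#' Nuclei whose angle profile lacks the required extrema are dropped (and
#' counted), mirroring the exclusion of unanalyzable swelled nuclei.
#'
#' @param fields List of [field_image]s.
#' @param seg_params [segmentation_params].
#' @param lm_params [landmark_params].
#' @param window_fraction Angle-profile window as a perimeter fraction.
#' @return List of records, each `list(field_idx, outline, oriented,
#'   landmarks, oriented_landmarks)`, with attribute `n_unanalyzable`.
#' @export
detect_and_orient <- function(fields, seg_params = segmentation_params(),
                              lm_params = landmark_params(),
                              window_fraction = 0.05) {
  records <- list()
  dropped <- 0
  for (fi in seq_along(fields)) {
    outlines <- detect_nuclei(fields[[fi]], seg_params)
    for (o in outlines) {
      rec <- tryCatch({
        prof <- compute_angle_profile(o, window_fraction)
        lms <- detect_landmarks(prof, o, lm_params)
        ori <- orient_nucleus(o, lms)
        list(field_idx = fi, outline = o, landmarks = lms,
             oriented = ori$outline, oriented_landmarks = ori$landmarks)
      }, nc_unanalyzable = function(e) NULL)
      if (is.null(rec)) dropped <- dropped + 1 else {
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  attr(records, "n_unanalyzable") <- dropped
  records
}

#' Warp a detected population onto a template and composite per probe
#'
#' Builds (or accepts) the template mesh, then for every nucleus and every
#' signal channel present in its field: crops the channel, binarises it
#' within the nucleus mask, and forward-warps it onto the template through
#' the nucleus's own mesh. Warps are grouped by probe label and composited.
#'
#' @param records Output of [detect_and_orient].
#' @param fields The same list of [field_image]s.
#' @param probe_map Per-field named character vectors mapping channel role
#'   to probe label, e.g. `list(c(signal_A = "chrX", signal_B = "chrY"), ...)`;
#'   recycled if length 1.
#' @param template Optional template: a [nucleus_mesh], or NULL to use the
#'   population consensus of `records`.
#' @param semilandmarks_per_segment Mesh resolution.
#' @param binarise_method Threshold spec for [binarise_signal].
#' @param points_per_segment Consensus resampling density.
#' @return List: `consensus`, `template_mesh`, `frame`, `warps` (list per
#'   probe of [warp_signal] results), `composites` (list per probe of
#'   [composite_map]).
#' @export
warp_population <- function(records, fields, probe_map,
                            template = NULL,
                            semilandmarks_per_segment = 20,
                            binarise_method = "otsu",
                            points_per_segment = 100) {
  if (length(records) == 0) stop("no nuclei to warp")
  if (!is.list(probe_map)) probe_map <- list(probe_map)
  if (length(probe_map) == 1) probe_map <- rep(probe_map, length(fields))
  consensus <- build_consensus(lapply(records, `[[`, "oriented"),
                               lapply(records, `[[`, "oriented_landmarks"),
                               points_per_segment)
  template_mesh <- if (is.null(template)) {
    build_mesh(consensus, semilandmarks_per_segment = semilandmarks_per_segment)
  } else template
  frame <- target_frame(template_mesh)
  warps <- list()
  for (rec in records) {
    mesh <- tryCatch(
      build_mesh(rec$oriented$boundary, rec$oriented_landmarks,
                 semilandmarks_per_segment),
      nc_degenerate_mesh = function(e) NULL)
    if (is.null(mesh)) next
    if (!mesh_isomorphic(mesh, template_mesh)) next
    fld <- fields[[rec$field_idx]]
    pm <- probe_map[[rec$field_idx]]
    for (role in names(pm)) {
      if (is.null(fld$channels[[role]])) next
      chan <- crop_channel(fld, rec$outline, role)
      bin <- binarise_signal(chan, rec$outline$mask, binarise_method)
      w <- warp_signal(mesh, template_mesh, bin,
                       pre_transform = rec$oriented$transform,
                       frame = frame, source_nucleus = rec$outline$id)
      lab <- pm[[role]]
      warps[[lab]] <- c(warps[[lab]], list(w))
    }
  }
  composites <- lapply(stats::setNames(names(warps), names(warps)), function(lab) {
    composite(warps[[lab]], probe_label = lab)
  })
  list(consensus = consensus, template_mesh = template_mesh, frame = frame,
       warps = warps, composites = composites)
}

#' Per-nucleus signal detections and centre-of-mass distances
#'
#' For every nucleus whose field carries both signal channels, detects the
#' discrete signals in each channel and returns the distance between the
#' centres of mass of the largest detection per channel.
#'
#' @param records Output of [detect_and_orient].
#' @param fields The field images.
#' @param probe_map As in [warp_population].
#' @param method,min_area_um2 Signal detection parameters.
#' @return Data frame: nucleus_id, probe_a, probe_b, distance_um.
#' @export
population_distances <- function(records, fields, probe_map,
                                 method = "fraction:0.5", min_area_um2 = 0.3) {
  if (!is.list(probe_map)) probe_map <- list(probe_map)
  if (length(probe_map) == 1) probe_map <- rep(probe_map, length(fields))
  rows <- list()
  for (rec in records) {
    fld <- fields[[rec$field_idx]]
    pm <- probe_map[[rec$field_idx]]
    if (length(pm) < 2) next
    mpp <- fld$calibration$microns_per_pixel
    dets <- lapply(names(pm), function(role) {
      if (is.null(fld$channels[[role]])) return(NULL)
      d <- detect_signals(crop_channel(fld, rec$outline, role),
                          rec$outline$mask, method, min_area_um2, mpp,
                          probe_label = pm[[role]], nucleus_id = rec$outline$id)
      if (length(d) == 0) return(NULL)
      d[[which.max(vapply(d, function(z) z$area_um2, numeric(1)))]]
    })
    if (any(vapply(dets, is.null, logical(1)))) next
    pd <- com_distance(dets[[1]], dets[[2]], fld$calibration)
    rows[[length(rows) + 1L]] <- data.frame(
      nucleus_id = pd$nucleus_id, probe_a = pd$probe_pair[1],
      probe_b = pd$probe_pair[2], distance_um = pd$distance_um,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(nucleus_id = character(0), probe_a = character(0),
                      probe_b = character(0), distance_um = numeric(0)))
  }
  do.call(rbind, rows)
}
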