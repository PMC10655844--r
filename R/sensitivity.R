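#' Cortical region of interest
#'
#' @param element_ids cortex triangle indices inside the ROI (non-empty).
#' @param name label.
#' @return object of class `seeg_roi`.
#' @export
roi <- function(element_ids, name = "ROI") {
  element_ids <- as.integer(element_ids)
  if (length(element_ids) == 0L) stop("ROI must contain at least one element")
  structure(list(element_ids = element_ids, name = name), class = "seeg_roi")
}

#' ROI from a spherical cap of the cortex
#'
#' Selects the cortical elements whose centroid direction (from the head
#' centre) lies within `half_angle` degrees of `axis` — a geometric stand-in
#' for a clinician-drawn region.
#'
#' @param cortex cortical `seeg_mesh`.
#' @param axis cap axis from the head centre.
#' @param half_angle cap half-angle (degrees).
#' @param name ROI label.
#' @param center head centre (mm).
#' @return a `seeg_roi`.
#' @export
cap_roi <- function(cortex, axis = c(1, 0, 0), half_angle = 45, name = "cap",
                    center = c(0, 0, 0)) {
  d <- cortex$centroids - matrix(center, nrow(cortex$centroids), 3, byrow = TRUE)
  d <- d / sqrt(rowSums(d^2))
  keep <- as.vector(d %*% unit(axis)) >= cos(deg2rad(half_angle))
  roi(which(keep), name)
}

roi_ids <- function(x) if (inherits(x, "seeg_roi")) x$element_ids else as.integer(x)

# columns of a patch lead field whose centre element lies in the ROI
roi_columns <- function(patch_lf, roi) {
  which(patch_lf$patch_centers %in% roi_ids(roi))
}

#' Patches recordable by a single electrode
#'
#' A patch is recordable by an electrode when at least two of the
#' electrode's contacts see a voltage magnitude at or above the threshold
#' (the two-contact rule required for source localization; the threshold
#' comparison is inclusive).
#'
#' @param patch_lf a `seeg_patch_lead_field` (µV).
#' @param electrode_contact_rows row indices of the electrode's contacts
#'   (1-16 rows).
#' @param thr detection threshold (µV): 200, 500 or 1000 in the standard
#'   analyses.
#' @param min_contacts contacts required at or above threshold (default 2).
#' @return logical vector, one entry per patch.
#' @export
recordable_by_electrode <- function(patch_lf, electrode_contact_rows, thr,
                                    min_contacts = 2L) {
  rows <- as.integer(electrode_contact_rows)
  if (length(rows) < 1L || length(rows) > 16L)
    stop("an electrode has between 1 and 16 contacts")
  if (any(rows < 1L | rows > nrow(patch_lf$matrix)))
    stop("unknown contact rows")
  hits <- abs(patch_lf$matrix[rows, , drop = FALSE]) >= thr
  colSums(hits) >= min_contacts
}

#' Recording strength per patch
#'
#' The number of electrodes in a configuration able to record each patch.
#'
#' @param patch_lf a `seeg_patch_lead_field`.
#' @param configuration list of electrodes, each an integer vector of
#'   contact rows.
#' @param thr threshold (µV).
#' @return integer vector, one count per patch.
#' @export
recording_strength <- function(patch_lf, configuration, thr) {
  strength <- integer(ncol(patch_lf$matrix))
  for (el in configuration)
    strength <- strength + recordable_by_electrode(patch_lf, el, thr)
  strength
}

#' Recording sensitivity of a configuration (RS)
#'
#' The percentage of patches with centre elements inside the ROI that are
#' recordable (recording strength >= 1) by the configuration:
#' `RS = 100 * P_recordable / P_total`.
#'
#' @inheritParams recording_strength
#' @param roi a [roi()] or integer vector of cortex element ids.
#' @return RS in percent.
#' @export
recording_sensitivity <- function(patch_lf, configuration, roi, thr) {
  cols <- roi_columns(patch_lf, roi)
  if (length(cols) == 0L) stop("ROI contains no patch centre elements")
  if (length(configuration) == 0L) return(0)
  sub <- patch_lf
  sub$matrix <- patch_lf$matrix[, cols, drop = FALSE]
  sub$patch_centers <- patch_lf$patch_centers[cols]
  100 * sum(recording_strength(sub, configuration, thr) >= 1L) / length(cols)
}

#' Unrecordable-patch count (optimization cost)
#'
#' The number of ROI patches not recordable by the configuration:
#' `C = P_total - P_recordable`. Always satisfies `C + P_recordable =
#' P_total`.
#'
#' @inheritParams recording_sensitivity
#' @return non-negative integer count.
#' @export
rs_cost <- function(patch_lf, configuration, roi, thr) {
  cols <- roi_columns(patch_lf, roi)
  if (length(cols) == 0L) stop("ROI contains no patch centre elements")
  p_total <- length(cols)
  rs <- recording_sensitivity(patch_lf, configuration, roi, thr)
  as.integer(round(p_total - rs * p_total / 100))
}

#' Estimate the recording radius of a set of contacts
#'
#' Patches are binned by centre-to-contact distance (0.25 cm half-open bins,
#' left-closed). Per contact and bin, the percentage of that bin's patches
#' with voltage magnitude at or above the threshold is computed; the
#' across-contact quantile (default the median, i.e. >= 50% of contacts) is
#' taken per bin, and the radius is the right edge of the farthest bin whose
#' quantile reaches `rs_floor` percent.
#'
#' @param patch_lf a `seeg_patch_lead_field` with contact and patch-centre
#'   positions (mm).
#' @param thr threshold (µV).
#' @param contacts contact row indices to include (default all).
#' @param bin_width bin size in cm (default 0.25).
#' @param rs_floor sensitivity floor in percent (default 20).
#' @param source_quantile fraction of contacts required to reach the floor
#'   (default 0.5: the median contact).
#' @return radius in cm. Attributes: `bin_rs` (quantile RS per bin),
#'   `bin_edges`, `no_bin_passed` flag, and `sparse_bins` (bins missing for
#'   some contact inside the occupied range, flagged rather than filled).
#' @export
estimate_recording_radius <- function(patch_lf, thr,
                                      contacts = seq_len(nrow(patch_lf$matrix)),
                                      bin_width = 0.25, rs_floor = 20,
                                      source_quantile = 0.5) {
  cp <- patch_lf$contact_positions[contacts, , drop = FALSE]
  pp <- patch_lf$patch_center_positions
  V <- abs(patch_lf$matrix[contacts, , drop = FALSE]) >= thr
  nb_max <- 0L
  per_contact <- vector("list", nrow(cp))
  for (i in seq_len(nrow(cp))) {
    d_cm <- sqrt(colSums((t(pp) - cp[i, ])^2)) / 10
    bin <- floor(d_cm / bin_width) + 1L          # [0, w), [w, 2w), ...
    rs <- tapply(V[i, ], bin, function(z) 100 * mean(z))
    per_contact[[i]] <- rs
    nb_max <- max(nb_max, max(bin))
  }
  M <- matrix(NA_real_, nrow(cp), nb_max)
  for (i in seq_len(nrow(cp)))
    M[i, as.integer(names(per_contact[[i]]))] <- per_contact[[i]]
  occupied <- colSums(!is.na(M)) > 0
  sparse <- which(apply(M, 2, anyNA) & occupied)
  bin_rs <- apply(M, 2, function(col)
    if (all(is.na(col))) NA_real_
    else as.numeric(quantile(col, probs = 1 - source_quantile, na.rm = TRUE,
                             type = 7)))
  pass <- which(!is.na(bin_rs) & bin_rs >= rs_floor)
  radius <- if (length(pass)) max(pass) * bin_width else 0
  attr(radius, "bin_rs") <- bin_rs
  attr(radius, "bin_edges") <- seq_len(nb_max) * bin_width
  attr(radius, "no_bin_passed") <- length(pass) == 0L
  attr(radius, "sparse_bins") <- sparse
  radius
}

#' Recording radius of an equivalent point dipole
#'
#' Desk-scale surrogate for the full extended-source analysis: a patch of
#' given area and moment density is collapsed to one on-axis point dipole of
#' total moment `area * density`, and the largest distance where the radial
#' potential magnitude reaches the threshold is reported on the 0.25 cm bin
#' grid (right edge of the last passing half-open bin).
#'
#' @param patch_area_cm2 patch area (cm^2).
#' @param moment_density dipole moment density (nA·m/mm^2).
#' @param thr threshold (µV).
#' @param model a [conductivity_model()].
#' @param bin_width bin size in cm.
#' @param max_cm search limit (cm).
#' @param step_mm on-axis sampling step (mm).
#' @return radius in cm; attribute `r_exact_cm` holds the unbinned
#'   threshold-crossing distance.
#' @export
recording_radius_point_dipole <- function(patch_area_cm2 = 10,
                                          moment_density = 0.465,
                                          thr = 500,
                                          model = conductivity_model(),
                                          bin_width = 0.25, max_cm = 10,
                                          step_mm = 0.01) {
  p_Am <- patch_area_cm2 * 100 * moment_density * 1e-9   # total moment, A·m
  r_mm <- seq(1, max_cm * 10, by = step_mm)
  v_uV <- abs(dipole_potential(c(0, 0, 0), c(0, 0, p_Am), cbind(0, 0, r_mm),
                               model)) * 1e6
  ok <- v_uV >= thr
  if (!any(ok)) {
    radius <- 0
    attr(radius, "r_exact_cm") <- 0
    return(radius)
  }
  r_exact <- max(r_mm[ok]) / 10
  radius <- (floor(r_exact / bin_width) + 1) * bin_width
  attr(radius, "r_exact_cm") <- r_exact
  radius
}

#' Partition the cortex into atlas-like subregions
#'
#' Splits each hemisphere (relative to the midline plane) into `n_regions`
#' cells of an equal-area polar/azimuthal grid, a geometric stand-in for a
#' cortical parcellation atlas.
#'
#' @param cortex cortical `seeg_mesh`.
#' @param n_regions regions per hemisphere (default 35 = 5 x 7 grid).
#' @param midline a [plane()] splitting the hemispheres.
#' @return data.frame with one row per triangle: `region` (1..n_regions)
#'   and `hemisphere` (1 or 2).
#' @export
atlas_labels <- function(cortex, n_regions = 35,
                         midline = plane(c(0, 0, 0), c(1, 0, 0))) {
  grid <- c(floor(sqrt(n_regions)), ceiling(n_regions / floor(sqrt(n_regions))))
  if (grid[1] * grid[2] < n_regions) grid[2] <- grid[2] + 1
  C <- cortex$centroids
  side <- as.vector((C - matrix(midline$point, nrow(C), 3, byrow = TRUE)) %*%
                      midline$normal)
  hemi <- ifelse(side >= 0, 1L, 2L)
  d <- C / sqrt(rowSums(C^2))
  # per-hemisphere chart: bands in |distance from midline|, sectors around
  # the midline normal, so every hemisphere covers the full sector range
  b <- plane_basis(midline$normal)
  u <- abs(as.vector(d %*% midline$normal))
  psi <- atan2(as.vector(d %*% b$v), as.vector(d %*% b$u))
  band <- pmin(floor(u * grid[1]), grid[1] - 1)
  sector <- pmin(floor((psi + pi) / (2 * pi) * grid[2]), grid[2] - 1)
  region <- (band * grid[2] + sector) %% n_regions + 1L
  data.frame(region = as.integer(region), hemisphere = hemi)
}

#' Sample simulated contact locations across cortical subregions
#'
#' Draws `per_region` area-weighted random cortex points from every
#' subregion of every hemisphere (35 regions x 3 points = 105 per hemisphere
#' with the defaults) and offsets them slightly inward so they do not
#' coincide with dipole locations.
#'
#' @param cortex cortical `seeg_mesh`.
#' @param labels data.frame from [atlas_labels()] (or compatible).
#' @param per_region points per region (default 3).
#' @param seed RNG seed.
#' @param offset_mm inward offset along the local normal (mm).
#' @param n_regions expected number of regions per hemisphere; a region with
#'   no elements raises an error.
#' @return matrix of contact points (mm) with attributes `region`,
#'   `hemisphere`, `element`.
#' @export
contact_sampling <- function(cortex, labels = atlas_labels(cortex),
                             per_region = 3, seed = 1L, offset_mm = 1,
                             n_regions = max(labels$region)) {
  cells <- split(seq_len(nrow(labels)),
                 list(factor(labels$hemisphere, levels = c(1L, 2L)),
                      factor(labels$region, levels = seq_len(n_regions))),
                 drop = FALSE)
  if (any(lengths(cells) == 0L))
    stop("a cortical subregion contains no elements")
  with_seed(seed, {
    picked <- lapply(cells, function(idx)
      idx[sample.int(length(idx), per_region,
                     replace = length(idx) < per_region,
                     prob = cortex$areas[idx])])
    el <- unlist(picked, use.names = FALSE)
    pts <- cortex$centroids[el, , drop = FALSE] -
      offset_mm * cortex$normals[el, , drop = FALSE]
    attr(pts, "element") <- el
    attr(pts, "region") <- labels$region[el]
    attr(pts, "hemisphere") <- labels$hemisphere[el]
    pts
  })
}
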