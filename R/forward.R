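#' Volume-conductor model
#'
#' The analytic forward model treats the head as an infinite homogeneous
#' conductor of conductivity `sigma`; the standard brain-tissue value
#' 0.33 S/m is the default. Externally computed lead fields (e.g. from a
#' patient-specific FEM) can replace it via [read_lead_field()].
#'
#' @param sigma conductivity in S/m (> 0).
#' @param kind currently only `"infinite_homogeneous"`.
#' @return object of class `seeg_conductivity`.
#' @export
conductivity_model <- function(sigma = 0.33, kind = "infinite_homogeneous") {
  kind <- match.arg(kind)
  if (sigma <= 0) stop("sigma must be > 0")
  structure(list(kind = kind, sigma = sigma), class = "seeg_conductivity")
}

#' Potential of a current dipole in an infinite homogeneous medium
#'
#' `V(r) = p . (r - r0) / (4 pi sigma |r - r0|^3)` with the reference at
#' infinity. Positions are millimetres, the moment is in A·m, the result in
#' volts.
#'
#' @param position dipole location (length-3, mm).
#' @param moment dipole moment vector (length-3, A·m).
#' @param observation_points n x 3 matrix (mm) or length-3 vector.
#' @param model a [conductivity_model()].
#' @param min_dist_mm singularity guard: observation points closer than this
#'   to the dipole raise an error.
#' @return numeric vector of potentials (V), one per observation point.
#' @export
dipole_potential <- function(position, moment, observation_points,
                             model = conductivity_model(), min_dist_mm = 0.1) {
  if (is.null(dim(observation_points)))
    observation_points <- matrix(observation_points, ncol = 3, byrow = TRUE)
  d <- (observation_points - matrix(position, nrow(observation_points), 3,
                                    byrow = TRUE)) * 1e-3   # mm -> m
  r <- sqrt(rowSums(d^2))
  if (any(r < min_dist_mm * 1e-3))
    stop("observation point within ", min_dist_mm, " mm of the dipole (singularity)")
  as.vector(d %*% moment) / (4 * pi * model$sigma * r^3)
}

#' Cortical dipole source set
#'
#' One current dipole per cortical element, located at the triangle centroid
#' and oriented along the outward triangle normal.
#'
#' @param cortex cortical `seeg_mesh`.
#' @param element_ids triangles to use (default: all).
#' @return object of class `seeg_sources`: `positions` (mm), `orientations`
#'   (unit), `element_areas` (mm^2), `element_ids`.
#' @export
cortical_sources <- function(cortex, element_ids = seq_len(nrow(cortex$triangles))) {
  ok <- cortex$areas[element_ids] > 0
  if (!all(ok)) stop("degenerate cortical elements cannot carry dipoles")
  structure(list(positions = cortex$centroids[element_ids, , drop = FALSE],
                 orientations = cortex$normals[element_ids, , drop = FALSE],
                 element_areas = cortex$areas[element_ids],
                 element_ids = as.integer(element_ids)),
            class = "seeg_sources")
}

#' Assemble a lead-field matrix
#'
#' Column k holds the potentials of a unit-moment (1 A·m) dipole at source k
#' evaluated at every contact, in V/(A·m).
#'
#' @param sources a [cortical_sources()] set.
#' @param contacts m x 3 matrix of contact positions (mm).
#' @param model a [conductivity_model()].
#' @param min_dist_mm singularity guard (mm).
#' @return object of class `seeg_lead_field`: `matrix` (contacts x sources),
#'   `contact_positions`, `source_ids`, `source_positions`,
#'   `source_areas`, `sigma`, `units = "V_per_Am"`.
#' @export
build_lead_field <- function(sources, contacts, model = conductivity_model(),
                             min_dist_mm = 0.1) {
  if (is.null(dim(contacts))) contacts <- matrix(contacts, ncol = 3, byrow = TRUE)
  contacts <- as.matrix(contacts)
  storage.mode(contacts) <- "double"
  M <- cpp_lead_field(sources$positions, sources$orientations, contacts,
                      model$sigma, min_dist_mm)
  structure(list(matrix = M, contact_positions = contacts,
                 source_ids = sources$element_ids,
                 source_positions = sources$positions,
                 source_areas = sources$element_areas,
                 sigma = model$sigma, units = "V_per_Am"),
            class = "seeg_lead_field")
}

#' @export
print.seeg_lead_field <- function(x, ...) {
  cat(sprintf("seeg_lead_field: %d contacts x %d sources [%s], sigma=%g S/m\n",
              nrow(x$matrix), ncol(x$matrix), x$units, x$sigma))
  invisible(x)
}

#' Re-reference a lead field to one of its contacts
#'
#' Subtracts the row of `reference` from every row, emulating a recording
#' reference at that contact instead of infinity.
#'
#' @param lead_field a `seeg_lead_field`.
#' @param reference contact row index.
#' @return re-referenced `seeg_lead_field`.
#' @export
apply_reference <- function(lead_field, reference) {
  M <- lead_field$matrix
  lead_field$matrix <- sweep(M, 2, M[reference, ], "-")
  lead_field
}

#' Write / read the lead-field container
#'
#' The container is a single JSON file holding the matrix, contact
#' positions, source ids and the attributes `units` ("V_per_Am") and
#' `sigma_S_per_m`; numbers are serialized at full precision so round-trips
#' are lossless.
#'
#' @param lead_field a `seeg_lead_field`.
#' @param path output path (.json).
#' @return `path` invisibly.
#' @export
write_lead_field <- function(lead_field, path) {
  payload <- list(units = lead_field$units,
                  sigma_S_per_m = lead_field$sigma,
                  contacts = lead_field$contact_positions,
                  source_ids = lead_field$source_ids,
                  source_positions = lead_field$source_positions,
                  source_areas = lead_field$source_areas,
                  matrix = lead_field$matrix)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_lead_field
#' @export
read_lead_field <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$units)) stop("lead-field container missing 'units' attribute")
  if (!identical(x$units, "V_per_Am"))
    stop("unsupported lead-field units: ", x$units)
  M <- as.matrix(x$matrix)
  if (anyNA(M) || !all(is.finite(M)))
    stop("lead-field matrix contains non-finite entries")
  if (ncol(M) != length(x$source_ids))
    stop("lead-field column count does not match source ids")
  contacts <- as.matrix(x$contacts)
  if (nrow(M) != nrow(contacts))
    stop("lead-field row count does not match contact positions")
  structure(list(matrix = M, contact_positions = contacts,
                 source_ids = as.integer(x$source_ids),
                 source_positions = if (!is.null(x$source_positions))
                   as.matrix(x$source_positions) else NULL,
                 source_areas = x$source_areas,
                 sigma = x$sigma_S_per_m, units = x$units),
            class = "seeg_lead_field")
}
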