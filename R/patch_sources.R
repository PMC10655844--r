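#' Assemble an extended-source (patch) lead field
#'
#' Each patch column is the sum of the member-dipole lead-field columns,
#' each scaled by its triangle area (mm^2) and by the cortical dipole moment
#' density (nA·m/mm^2). Unit bookkeeping: V/(A·m) x mm^2 x nA·m/mm^2 gives
#' nV x 1e0, i.e. 1e-3 µV, so the assembled matrix is in microvolts after a
#' single 1e-3 factor. Voltages stay signed; magnitudes are taken only when
#' thresholding.
#'
#' @param lead_field a `seeg_lead_field` over single dipoles.
#' @param patches a `seeg_patch_set` (member ids must be lead-field source
#'   ids).
#' @param moment_density dipole moment density in nA·m/mm^2.
#' @return object of class `seeg_patch_lead_field`: `matrix` (contacts x
#'   patches, µV), `patch_area` (cm^2), `moment_density`, `patch_centers`,
#'   `patch_center_positions`, `contact_positions`.
#' @export
build_patch_lead_field <- function(lead_field, patches, moment_density) {
  ids <- lead_field$source_ids
  col_of <- integer(max(c(ids, 1L)))
  col_of[ids] <- seq_along(ids)
  np <- length(patches$members)
  mem_all <- unlist(patches$members, use.names = FALSE)
  if (any(mem_all > length(col_of)) || any(col_of[mem_all] == 0L))
    stop("a patch references an element missing from the lead field")
  i <- col_of[mem_all]
  j <- rep.int(seq_len(np), lengths(patches$members))
  x <- lead_field$source_areas[i]
  W <- Matrix::sparseMatrix(i = i, j = j, x = x * moment_density * 1e-3,
                            dims = c(length(ids), np))
  M <- as.matrix(lead_field$matrix %*% W)
  centers <- patches$centers
  pos <- lead_field$source_positions[match(centers, ids), , drop = FALSE]
  structure(list(matrix = M, patch_area = patches$target_area,
                 moment_density = moment_density,
                 patch_centers = as.integer(centers),
                 patch_center_positions = pos,
                 contact_positions = lead_field$contact_positions),
            class = "seeg_patch_lead_field")
}

#' @export
print.seeg_patch_lead_field <- function(x, ...) {
  cat(sprintf("seeg_patch_lead_field: %d contacts x %d patches (area %g cm^2, density %g nA.m/mm^2)\n",
              nrow(x$matrix), ncol(x$matrix), x$patch_area, x$moment_density))
  invisible(x)
}

#' Patch lead fields for the full source-parameter grid
#'
#' Builds one patch lead field per (area, density) pair. The defaults are
#' the three physiologically plausible patch areas (6, 10, 20 cm^2) crossed
#' with the minimum, mean and maximum neocortical dipole moment densities
#' (0.16, 0.465, 0.77 nA·m/mm^2); the (10 cm^2, 0.465) pair is tagged as the
#' default source used in the main analyses.
#'
#' @param lead_field a `seeg_lead_field` whose sources cover the mesh.
#' @param mesh cortical `seeg_mesh` (for patch growth).
#' @param areas patch areas in cm^2.
#' @param densities dipole moment densities in nA·m/mm^2.
#' @param centers patch centre elements (default: every lead-field source).
#' @return named list of `seeg_patch_lead_field` (names like `a10_d0.465`);
#'   the default pair carries attribute `default = TRUE`, and the list has
#'   attribute `patch_sets` (one `seeg_patch_set` per area).
#' @export
source_grid <- function(lead_field, mesh, areas = c(6, 10, 20),
                        densities = c(0.16, 0.465, 0.77),
                        centers = lead_field$source_ids) {
  adjacency <- triangle_adjacency(mesh)
  patch_sets <- lapply(areas, function(a)
    grow_patches(mesh, a, centers = centers, adjacency = adjacency))
  names(patch_sets) <- paste0("a", areas)
  out <- list()
  for (k in seq_along(areas)) {
    for (d in densities) {
      plf <- build_patch_lead_field(lead_field, patch_sets[[k]], d)
      nm <- paste0("a", areas[k], "_d", d)
      if (isTRUE(all.equal(areas[k], 10)) && isTRUE(all.equal(d, 0.465)))
        attr(plf, "default") <- TRUE
      out[[nm]] <- plf
    }
  }
  attr(out, "patch_sets") <- patch_sets
  out
}
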