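# per-trajectory recordable matrix at one threshold, restricted to ROI columns:
# entry (i, j) is TRUE when trajectory i records ROI patch j at >= 2 contacts
recordable_matrix <- function(patch_lf, contact_rows, cols, thr) {
  B <- abs(patch_lf$matrix[, cols, drop = FALSE]) >= thr
  n <- nrow(contact_rows)
  G <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(contact_rows)),
                            j = as.vector(contact_rows), x = 1,
                            dims = c(n, nrow(patch_lf$matrix)))
  as.matrix(G %*% B) >= 2
}

# shared greedy engine: pick, among `active` candidates, the one with maximal
# newly-covered patch count at the priority threshold, breaking ties at the
# secondary then tertiary threshold and finally by a seeded random draw
greedy_pick <- function(R_list, covered, active, seed, step) {
  cand <- which(active)
  gains <- function(Rm, cov) {
    un <- which(!cov)
    if (length(un) == 0L) return(integer(length(cand)))
    as.integer(rowSums(R_list[[Rm]][cand, un, drop = FALSE]))
  }
  g1 <- gains(1L, covered[[1]])
  best <- max(g1)
  tie <- cand[g1 == best]
  if (length(tie) > 1L) {
    g2 <- as.integer(rowSums(R_list[[2]][tie, !covered[[2]], drop = FALSE]))
    tie <- tie[g2 == max(g2)]
  }
  if (length(tie) > 1L) {
    g3 <- as.integer(rowSums(R_list[[3]][tie, !covered[[3]], drop = FALSE]))
    tie <- tie[g3 == max(g3)]
  }
  pick <- if (length(tie) > 1L)
    with_seed(seed + 7919L * step, tie[sample.int(length(tie), 1L)])
  else tie[1L]
  list(pick = pick, gain = best)
}

#' Next-best greedy search for an electrode configuration
#'
#' Iteratively adds the valid, non-colliding trajectory that maximally
#' decreases the number of unrecordable ROI patches at the priority
#' threshold. Ties are broken by the cost decrease at the secondary and then
#' tertiary priority thresholds, and finally by a seeded random choice.
#' The search stops after `max_electrodes` electrodes or when no remaining
#' candidate improves the priority cost. Because the search is iterative,
#' the optimized configuration of any size X is the first X electrodes.
#'
#' @param ts a `seeg_trajectory_set` with its collision matrix computed.
#' @param patch_lf a `seeg_patch_lead_field` whose rows match `contact_rows`.
#' @param roi a [roi()] (or element-id vector).
#' @param contact_rows n_traj x n_contacts matrix of patch-lead-field rows,
#'   from [contact_table()].
#' @param priority threshold-priority order: permutation of the three
#'   detection thresholds, primary first (default 500, 200, 1000 µV).
#' @param max_electrodes maximum electrodes to add (default 31).
#' @param seed seed for the tie-break generator (recorded in the result).
#' @return object of class `seeg_config`: `electrodes` (trajectory row
#'   indices, in selection order), `contact_rows`, `contact_points`,
#'   `shaft_points`, `cost_curve` (step x threshold), `priority`, `seed`,
#'   `P_total`, `rs_report`.
#' @export
next_best_search <- function(ts, patch_lf, roi, contact_rows,
                             priority = c(500, 200, 1000),
                             max_electrodes = 31, seed = 1L) {
  if (!inherits(ts, "seeg_trajectory_set")) stop("ts must be a trajectory set")
  n <- nrow(ts$trajectories)
  if (n == 0L) stop("empty candidate trajectory set")
  if (is.null(ts$collision)) stop("collision matrix missing: run collision_matrix() first")
  if (length(priority) != 3L || anyDuplicated(priority) > 0L)
    stop("priority must be three distinct thresholds")
  cols <- roi_columns(patch_lf, roi)
  if (length(cols) == 0L) stop("ROI contains no patch centre elements")
  R_list <- lapply(priority, function(thr)
    recordable_matrix(patch_lf, contact_rows, cols, thr))
  p_total <- length(cols)
  covered <- rep(list(rep(FALSE, p_total)), 3L)
  active <- rep(TRUE, n)
  chosen <- integer(0)
  cost_curve <- matrix(NA_real_, 0, 3, dimnames = list(NULL, priority))
  step <- 0L
  while (length(chosen) < max_electrodes && any(active)) {
    step <- step + 1L
    sel <- greedy_pick(R_list, covered, active, seed, step)
    if (sel$gain == 0L) break
    chosen <- c(chosen, sel$pick)
    for (k in 1:3) covered[[k]] <- covered[[k]] | R_list[[k]][sel$pick, ]
    active[sel$pick] <- FALSE
    active[ts$collision[sel$pick, ]] <- FALSE
    cost_curve <- rbind(cost_curve,
                        p_total - vapply(covered, sum, numeric(1)))
  }
  config <- new_seeg_config(ts, chosen, contact_rows, cost_curve, priority,
                            seed, p_total, roi)
  config$rs_report <- rs_curves(config, patch_lf, roi)
  config
}

new_seeg_config <- function(ts, chosen, contact_rows, cost_curve, priority,
                            seed, p_total, roi) {
  traj <- ts$trajectories[chosen, , drop = FALSE]
  cp <- if (length(chosen)) trajectory_contacts(traj, ts$electrode) else NULL
  sp <- if (length(chosen)) trajectory_shaft_points(traj, ts$shaft_samples) else NULL
  structure(list(electrodes = chosen,
                 trajectories = traj,
                 contact_rows = contact_rows[chosen, , drop = FALSE],
                 contact_points = cp, shaft_points = sp,
                 cost_curve = cost_curve, priority = priority,
                 seed = seed, P_total = p_total,
                 roi_name = if (inherits(roi, "seeg_roi")) roi$name else "ROI",
                 rs_report = NULL),
            class = "seeg_config")
}

#' RS curves of a configuration
#'
#' Recording sensitivity of every configuration prefix at the three
#' detection thresholds, plus the per-patch recording strength of the full
#' configuration.
#'
#' @param config a `seeg_config`.
#' @param patch_lf the patch lead field the configuration was built on.
#' @param roi the ROI.
#' @param thresholds thresholds (µV) for the curves.
#' @return object of class `seeg_rs_report`: `thresholds`, `rs_by_count`
#'   (prefix x threshold, percent), `P_total`, `P_i` (final recordable
#'   counts), `recording_strength` (all patches x thresholds),
#'   `patch_centers`.
#' @export
rs_curves <- function(config, patch_lf, roi,
                      thresholds = sort(config$priority)) {
  cols <- roi_columns(patch_lf, roi)
  k <- length(config$electrodes)
  R_list <- lapply(thresholds, function(thr)
    if (k) recordable_matrix(patch_lf, config$contact_rows, cols, thr))
  rs <- matrix(0, k, length(thresholds),
               dimnames = list(NULL, thresholds))
  for (t in seq_along(thresholds)) {
    if (k == 0) break
    cum <- rep(FALSE, length(cols))
    for (i in seq_len(k)) {
      cum <- cum | R_list[[t]][i, ]
      rs[i, t] <- 100 * sum(cum) / length(cols)
    }
  }
  electrodes <- split(as.vector(t(config$contact_rows)),
                      rep(seq_len(k), each = ncol(config$contact_rows)))
  strength <- vapply(thresholds, function(thr)
    recording_strength(patch_lf, electrodes, thr),
    integer(ncol(patch_lf$matrix)))
  colnames(strength) <- thresholds
  p_i <- if (k > 0) round(rs[k, ] * length(cols) / 100)
         else setNames(rep(0, length(thresholds)), thresholds)
  structure(list(thresholds = thresholds, rs_by_count = rs,
                 P_total = length(cols),
                 P_i = p_i,
                 recording_strength = strength,
                 patch_centers = patch_lf$patch_centers),
            class = "seeg_rs_report")
}

#' @export
print.seeg_rs_report <- function(x, ...) {
  k <- nrow(x$rs_by_count)
  cat(sprintf("seeg_rs_report: %d electrodes, P_total=%d\n", k, x$P_total))
  if (k > 0) {
    final <- x$rs_by_count[k, ]
    cat("  final RS (%):",
        paste(sprintf("%s µV: %.1f", colnames(x$rs_by_count), final),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.seeg_config <- function(x, ...) {
  cat(sprintf("seeg_config: %d electrodes for %s (priority %s µV, seed %d)\n",
              length(x$electrodes), x$roi_name,
              paste(x$priority, collapse = "/"), x$seed))
  if (!is.null(x$rs_report) && length(x$electrodes))
    cat(sprintf("  final RS at priority threshold: %.1f%% of %d patches\n",
                x$rs_report$rs_by_count[length(x$electrodes),
                                        as.character(x$priority[1])],
                x$rs_report$P_total))
  invisible(x)
}

#' @export
summary.seeg_config <- function(object, ...) {
  print(object)
  if (!is.null(object$rs_report)) {
    cat("  RS by electrode count (%):\n")
    print(round(object$rs_report$rs_by_count, 1))
  }
  invisible(object)
}

#' @export
plot.seeg_config <- function(x, ...) {
  if (is.null(x$rs_report) || length(x$electrodes) == 0)
    stop("nothing to plot: empty configuration")
  rs <- x$rs_report$rs_by_count
  graphics::matplot(seq_len(nrow(rs)), rs, type = "b", pch = 1:3,
                    xlab = "electrodes", ylab = "RS (%)",
                    ylim = c(0, 100), ...)
  graphics::legend("bottomright", legend = paste(colnames(rs), "µV"),
                   col = 1:3, pch = 1:3, lty = 1:3)
  invisible(x)
}

#' Best ordering of a fixed (e.g. clinically implanted) electrode set
#'
#' Greedily orders the given electrodes so that each addition maximally
#' decreases the cost at the primary threshold, with the same tie rules as
#' [next_best_search()]; no selection takes place — all electrodes are
#' ordered.
#'
#' @param contact_rows k x n_contacts matrix of patch-lead-field rows, one
#'   electrode per row.
#' @param patch_lf the patch lead field.
#' @param roi the ROI.
#' @param thr primary threshold (µV); the remaining two standard thresholds
#'   act as secondary/tertiary tie-breakers in ascending order.
#' @param thresholds the full threshold set.
#' @param seed tie-break seed.
#' @return list with `order` (permutation of electrode indices), `rs_curve`
#'   (RS at each prefix, primary threshold), `cost_curve`.
#' @export
best_order <- function(contact_rows, patch_lf, roi, thr = 500,
                       thresholds = c(200, 500, 1000), seed = 1L) {
  k <- nrow(contact_rows)
  if (k == 0L) stop("empty electrode set")
  priority <- c(thr, sort(setdiff(thresholds, thr)))
  cols <- roi_columns(patch_lf, roi)
  R_list <- lapply(priority, function(t)
    recordable_matrix(patch_lf, contact_rows, cols, t))
  covered <- rep(list(rep(FALSE, length(cols))), 3L)
  active <- rep(TRUE, k)
  ord <- integer(0)
  rs_curve <- numeric(0)
  cost_curve <- numeric(0)
  for (step in seq_len(k)) {
    sel <- greedy_pick(R_list, covered, active, seed, step)
    ord <- c(ord, sel$pick)
    for (j in 1:3) covered[[j]] <- covered[[j]] | R_list[[j]][sel$pick, ]
    active[sel$pick] <- FALSE
    rs_curve <- c(rs_curve, 100 * sum(covered[[1]]) / length(cols))
    cost_curve <- c(cost_curve, length(cols) - sum(covered[[1]]))
  }
  list(order = ord, rs_curve = rs_curve, cost_curve = cost_curve)
}

#' Does an electrode belong to an ROI-targeting configuration?
#'
#' TRUE when at least one contact lies within `near` mm of the ROI surface
#' and at least half of the contacts lie within `far` mm of it.
#'
#' @param contact_points n_contacts x 3 matrix of contact centres (mm).
#' @param roi_surface `seeg_mesh` (or `seeg_distance_index`) of the ROI
#'   surface.
#' @param near near-contact distance (mm, default 3).
#' @param far half-of-contacts distance (mm, default 100).
#' @return logical scalar.
#' @export
electrode_in_roi <- function(contact_points, roi_surface, near = 3, far = 100) {
  d <- min_distance(roi_surface, contact_points)
  min(d) <= near && sum(d <= far) >= ceiling(length(d) / 2)
}

#' Precomputed source/patch/sulci context of a head model
#'
#' Bundles everything needed to evaluate configurations on a head: cortical
#' sources, the patch set of the default area, and the sulci surface with
#' its distance index.
#'
#' @param head a `seeg_head`.
#' @param patch_area patch area (cm^2).
#' @param smooth_iters sulci-hull smoothing iterations.
#' @return list with `head`, `sources`, `patches`, `sulci`, `sulci_index`.
#' @export
head_context <- function(head, patch_area = 10, smooth_iters = 100) {
  sources <- cortical_sources(head$cortex)
  patches <- grow_patches(head$cortex, patch_area)
  sulci <- derive_sulci_surface(head$cortex, smooth_iters)
  sulci_index <- if (nrow(sulci$triangles) > 0) distance_index(sulci) else NULL
  list(head = head, sources = sources, patches = patches,
       sulci = sulci, sulci_index = sulci_index)
}

#' Transfer a configuration to another head by a rigid transform
#'
#' Maps the configuration's contact and shaft points with a rotation +
#' translation (6 degrees of freedom; scaling and reflection are rejected),
#' recomputes the forward solution at the transferred contact locations on
#' the target head, and compares RS against the matched (source-head) case
#' at the minimum electrode count that reached `rs_target` percent RS in
#' the matched case. Electrodes passing within `sulci_clearance` of the
#' target sulci make the transferred configuration invalid, but all
#' electrodes are retained in the RS computation (best-case sensitivity).
#'
#' @param config a `seeg_config` with its `rs_report`.
#' @param transform list with rotation `R` (3 x 3) and translation `t`
#'   (length 3, mm).
#' @param target a [head_context()] for the target head.
#' @param target_roi ROI on the target cortex.
#' @param thr threshold (µV, default 500).
#' @param moment_density dipole moment density (nA·m/mm^2).
#' @param rs_target matched-case RS level defining the electrode count
#'   (percent, default 75).
#' @param sulci_clearance validity clearance to the target sulci (mm,
#'   default 2.5).
#' @param model a [conductivity_model()].
#' @return list with `n_at` (electrode count used), `rs_matched`,
#'   `rs_transferred` (percent), `percent_reduction`, `electrode_valid`
#'   (logical per electrode), `config_valid`, `reached_target`.
#' @export
transfer_configuration <- function(config, transform, target, target_roi,
                                   thr = 500, moment_density = 0.465,
                                   rs_target = 75, sulci_clearance = 2.5,
                                   model = conductivity_model()) {
  R <- transform$R
  tv <- transform$t
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("transform must be a proper rotation + translation (no scaling/reflection)")
  k <- length(config$electrodes)
  if (k == 0L) stop("empty configuration")
  rs_m <- config$rs_report$rs_by_count[, as.character(thr)]
  reached <- any(rs_m >= rs_target)
  n_at <- if (reached) min(which(rs_m >= rs_target)) else k
  rs_matched <- rs_m[n_at]

  map <- function(P) P %*% t(R) + matrix(tv, nrow(P), 3, byrow = TRUE)
  nc <- dim(config$contact_points)[2]
  contacts <- do.call(rbind, lapply(seq_len(n_at), function(i)
    map(config$contact_points[i, , ])))
  lf <- build_lead_field(target$sources, contacts, model)
  plf <- build_patch_lead_field(lf, target$patches, moment_density)
  electrodes <- split(seq_len(n_at * nc), rep(seq_len(n_at), each = nc))
  rs_transferred <- recording_sensitivity(plf, electrodes, target_roi, thr)

  valid <- vapply(seq_len(n_at), function(i) {
    if (is.null(target$sulci_index)) return(TRUE)
    min(min_distance(target$sulci_index, map(config$shaft_points[i, , ]))) >=
      sulci_clearance
  }, logical(1))
  list(n_at = n_at,
       rs_matched = as.numeric(rs_matched),
       rs_transferred = rs_transferred,
       percent_reduction = if (rs_matched > 0)
         100 * (rs_matched - rs_transferred) / rs_matched else NA_real_,
       electrode_valid = valid,
       config_valid = all(valid),
       reached_target = reached)
}
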