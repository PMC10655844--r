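#' Specification of a parametric synthetic head
#'
#' Describes a three-surface head (scalp, inner skull, cortex) built from
#' subdivided icospheres. The cortex is radially modulated by a product of
#' sinusoids in the spherical angles so that outward bulges ("gyri") and
#' inward troughs ("sulci") exist whenever `fold_amplitude > 0`. The midline
#' is an explicit plane, and candidate electrode entries are restricted to a
#' spherical cap on the scalp.
#'
#' @param scalp_radius scalp sphere radius (mm).
#' @param skull_radius inner-skull sphere radius (mm); must be < scalp.
#' @param cortex_base_radius unperturbed cortex radius (mm).
#' @param fold_amplitude radial fold amplitude (mm); 0 gives a smooth sphere.
#' @param fold_frequency integer angular frequency of the folds.
#' @param mesh_subdivision icosphere subdivision rounds for the cortex
#'   (>= 2); scalp and skull use one round less (they are smooth surfaces).
#' @param midline a [plane()]; the default is the x = 0 sagittal plane.
#' @param entry_cap list with `axis` (direction from head centre) and
#'   `half_angle` (degrees, in (0, 90]) bounding the implantation area.
#' @param seed integer seed recorded in the model and used by downstream
#'   samplers.
#' @return object of class `seeg_head_spec`.
#' @export
synthetic_head_spec <- function(scalp_radius = 92, skull_radius = 87,
                                cortex_base_radius = 70, fold_amplitude = 8,
                                fold_frequency = 6, mesh_subdivision = 4,
                                midline = plane(c(0, 0, 0), c(1, 0, 0)),
                                entry_cap = list(axis = c(1, 0, 0), half_angle = 50),
                                seed = 1L) {
  spec <- list(scalp_radius = scalp_radius, skull_radius = skull_radius,
               cortex_base_radius = cortex_base_radius,
               fold_amplitude = fold_amplitude,
               fold_frequency = as.integer(fold_frequency),
               mesh_subdivision = as.integer(mesh_subdivision),
               midline = midline, entry_cap = entry_cap, seed = as.integer(seed))
  if (!(scalp_radius > skull_radius))
    stop("scalp_radius must exceed skull_radius")
  if (!(skull_radius > cortex_base_radius + fold_amplitude))
    stop("skull_radius must exceed cortex_base_radius + fold_amplitude")
  if (fold_amplitude < 0) stop("fold_amplitude must be >= 0")
  if (spec$mesh_subdivision < 2L) stop("mesh_subdivision must be >= 2")
  ha <- entry_cap$half_angle
  if (is.null(ha) || ha <= 0 || ha > 90)
    stop("entry_cap half_angle must be in (0, 90] degrees")
  structure(spec, class = "seeg_head_spec")
}

#' Generate a synthetic head model
#'
#' Builds closed, outward-oriented scalp, inner-skull and cortex meshes from
#' a [synthetic_head_spec()]. Construction is fully deterministic; the seed
#' is carried along for downstream stochastic stages.
#'
#' @param spec a `seeg_head_spec`.
#' @return object of class `seeg_head`: `scalp`, `skull`, `cortex`
#'   (`seeg_mesh`), `midline`, `entry_cap`, `spec`.
#' @export
make_synthetic_head <- function(spec = synthetic_head_spec()) {
  if (!inherits(spec, "seeg_head_spec")) spec <- do.call(synthetic_head_spec, spec)
  outer_div <- max(spec$mesh_subdivision - 1L, 2L)
  scalp <- icosphere(spec$scalp_radius, outer_div)
  skull <- icosphere(spec$skull_radius, outer_div)
  cortex <- icosphere(1, spec$mesh_subdivision)
  V <- cortex$vertices
  r <- sqrt(rowSums(V^2))
  theta <- acos(pmin(pmax(V[, 3] / r, -1), 1))
  phi <- atan2(V[, 2], V[, 1])
  radius <- spec$cortex_base_radius +
    spec$fold_amplitude * sin(spec$fold_frequency * theta) *
    cos(spec$fold_frequency * phi)
  cortex <- orient_outward(surface_mesh(V * radius, cortex$triangles))
  structure(list(scalp = scalp, skull = skull, cortex = cortex,
                 midline = spec$midline, entry_cap = spec$entry_cap,
                 spec = spec),
            class = "seeg_head")
}

#' @export
print.seeg_head <- function(x, ...) {
  cat(sprintf(paste0("seeg_head: scalp r=%g mm (%d tri), skull r=%g mm, ",
                     "cortex base r=%g mm (%d tri), folds %g mm x f=%d\n"),
              x$spec$scalp_radius, nrow(x$scalp$triangles),
              x$spec$skull_radius, x$spec$cortex_base_radius,
              nrow(x$cortex$triangles), x$spec$fold_amplitude,
              x$spec$fold_frequency))
  invisible(x)
}

#' Specification of a synthetic sEEG-like voltage trace
#'
#' @param n_channels number of recording channels (>= 1).
#' @param n_samples samples per channel.
#' @param sample_rate sampling rate (Hz).
#' @param noise_sd Gaussian background noise SD (µV), >= 0.
#' @param spike_amplitudes peak amplitudes (µV) of the planted spikes.
#' @param spike_times sample indices of the spike onsets (1-based, within
#'   the trace).
#' @param spike_channels channel receiving each spike (recycled; default 1).
#' @param seed RNG seed.
#' @return object of class `seeg_trace_spec`.
#' @export
trace_spec <- function(n_channels = 4, n_samples = 10000, sample_rate = 1000,
                       noise_sd = 50, spike_amplitudes = numeric(0),
                       spike_times = integer(0), spike_channels = 1L,
                       seed = 1L) {
  if (n_channels < 1) stop("n_channels must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(spike_amplitudes) != length(spike_times))
    stop("spike_amplitudes and spike_times must have equal length")
  if (length(spike_times) && (min(spike_times) < 1 || max(spike_times) > n_samples))
    stop("spike times must lie within the trace")
  structure(list(n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples),
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 spike_amplitudes = spike_amplitudes,
                 spike_times = as.integer(spike_times),
                 spike_channels = rep_len(as.integer(spike_channels),
                                          length(spike_times)),
                 seed = as.integer(seed)),
            class = "seeg_trace_spec")
}

# biphasic triangular spike template, 60 ms wide, peak amplitude `amp` (µV)
spike_template <- function(amp, sample_rate) {
  n <- max(round(0.06 * sample_rate), 4)
  t <- seq(0, 1, length.out = n)
  shape <- ifelse(t < 0.25, t / 0.25,
                  ifelse(t < 0.75, 1 - (t - 0.25) / 0.5 * 1.5,
                         -0.5 + (t - 0.75) / 0.25 * 0.5))
  amp * shape
}

#' Generate a synthetic sEEG-like voltage trace
#'
#' Per-channel Gaussian noise plus biphasic triangular spikes of given peak
#' amplitudes at given onsets. A spike-free sample mask is returned so noise
#' statistics can be computed away from the planted events.
#'
#' @param spec a [trace_spec()].
#' @return object of class `seeg_trace`: `voltages` (channels x samples,
#'   µV), `sample_rate`, `spike_free_mask` (logical per sample),
#'   `spike_windows` (list of c(start, end)), `spec`.
#' @export
make_trace <- function(spec = trace_spec()) {
  V <- with_seed(spec$seed,
                 matrix(rnorm(spec$n_channels * spec$n_samples, 0, spec$noise_sd),
                        spec$n_channels, spec$n_samples))
  mask <- rep(TRUE, spec$n_samples)
  windows <- list()
  for (i in seq_along(spec$spike_times)) {
    tpl <- spike_template(spec$spike_amplitudes[i], spec$sample_rate)
    s <- spec$spike_times[i]
    e <- min(s + length(tpl) - 1L, spec$n_samples)
    ch <- spec$spike_channels[i]
    V[ch, s:e] <- V[ch, s:e] + tpl[seq_len(e - s + 1L)]
    mask[s:e] <- FALSE
    windows[[i]] <- c(s, e)
  }
  structure(list(voltages = V, sample_rate = spec$sample_rate,
                 spike_free_mask = mask, spike_windows = windows, spec = spec),
            class = "seeg_trace")
}

#' @export
print.seeg_trace <- function(x, ...) {
  cat(sprintf("seeg_trace: %d channels x %d samples @ %g Hz, %d spikes\n",
              nrow(x$voltages), ncol(x$voltages), x$sample_rate,
              length(x$spike_windows)))
  invisible(x)
}

#' Write / read a trace as CSV (samples x channels, named header)
#' @param trace a `seeg_trace` (or any channels x samples matrix).
#' @param path CSV path.
#' @return `path` invisibly / a voltage matrix (channels x samples).
#' @export
write_trace <- function(trace, path) {
  V <- if (inherits(trace, "seeg_trace")) trace$voltages else trace
  df <- as.data.frame(t(V))
  names(df) <- sprintf("ch%02d", seq_len(nrow(V)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  t(as.matrix(read.csv(path)))
}

#' Deterministic toy lead field for metric unit tests
#'
#' Contacts sit at the origin and sources along the +x axis, so the voltage
#' seen by contact i from source j is `decay_law(distance_ij)`. With a step
#' law this builds exact fixtures for recording-radius estimation.
#'
#' @param n_contacts,n_sources matrix dimensions (>= 1).
#' @param decay_law vectorized function mapping distance (mm) to voltage
#'   magnitude (µV); may use the RNG (seeded).
#' @param seed RNG seed applied around the `decay_law` calls.
#' @param contact_positions,source_positions optional explicit geometries
#'   (n x 3 mm); defaults: contacts at the origin, sources at
#'   x = 1.25, 3.75, 6.25, ... mm.
#' @return a `seeg_patch_lead_field` with the toy matrix (µV), contact
#'   positions and source ("patch centre") positions.
#' @export
make_toy_leadfield <- function(n_contacts, n_sources, decay_law, seed = 1L,
                               contact_positions = NULL, source_positions = NULL) {
  if (n_contacts < 1 || n_sources < 1) stop("dimensions must be >= 1")
  if (is.null(contact_positions))
    contact_positions <- matrix(0, n_contacts, 3)
  if (is.null(source_positions))
    source_positions <- cbind(1.25 + 2.5 * (seq_len(n_sources) - 1), 0, 0)
  D <- matrix(0, n_contacts, n_sources)
  for (i in seq_len(n_contacts))
    D[i, ] <- sqrt(colSums((t(source_positions) - contact_positions[i, ])^2))
  M <- with_seed(seed, matrix(decay_law(D), n_contacts, n_sources))
  structure(list(matrix = M, patch_area = NA_real_, moment_density = NA_real_,
                 patch_centers = seq_len(n_sources),
                 patch_center_positions = source_positions,
                 contact_positions = contact_positions),
            class = "seeg_patch_lead_field")
}
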