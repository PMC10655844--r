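# Full-scale synthetic study used by the acceptance-level checks:
# subdivision-4 cortex (5120 patch sources), ~2000 candidate trajectories,
# default 10 cm^2 / 0.465 nA·m/mm^2 source. Built once per test run.
fixture_study <- function() fixture("study", function() {
  head <- make_synthetic_head(synthetic_head_spec(mesh_subdivision = 4))
  sulci <- derive_sulci_surface(head$cortex)
  cand <- candidate_trajectories(head, n_entries = 30, n_angles = 8, seed = 1)
  ts <- filter_valid(cand, sulci, head$skull, head$midline)
  ts <- collision_matrix(ts)
  ct <- contact_table(ts)
  lf <- build_lead_field(cortical_sources(head$cortex), ct$points)
  patches <- grow_patches(head$cortex, 10)
  plf <- build_patch_lead_field(lf, patches, 0.465)
  list(head = head, sulci = sulci, ts = ts, ct = ct, lf = lf,
       patches = patches, plf = plf,
       roi = cap_roi(head$cortex, c(1, 0.3, 0.2), 45))
})

# seeded random valid (pairwise non-colliding) configuration of size k,
# returned as trajectory indices
random_valid_config <- function(ts, k, seed) {
  with_seed(seed, {
    n <- nrow(ts$trajectories)
    for (try in 1:50) {
      active <- rep(TRUE, n)
      sel <- integer(0)
      while (length(sel) < k && any(active)) {
        pick <- which(active)[sample.int(sum(active), 1)]
        sel <- c(sel, pick)
        active[pick] <- FALSE
        active[ts$collision[pick, ]] <- FALSE
      }
      if (length(sel) == k) return(sel)
    }
    stop("could not sample a non-colliding configuration of size ", k)
  })
}
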