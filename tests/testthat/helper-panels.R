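# small deterministic panels and seeded random panels shared across tests

make_panel <- function(ka, kd, n, c0, N0 = 1e-9,
                       names = paste0("S", seq_along(ka))) {
  corona_system(
    tibble::tibble(name = names, ka = ka, kd = kd, n = n, c0 = c0),
    N0 = N0
  )
}

# seeded random panel in the two-phase regime
rand_panel <- function(seed, m = 3) {
  generate_panel(panel_ranges(m = m), seed = seed)
}

# association-only panel with guaranteed >= `excess`-fold protein excess
assoc_panel <- function(seed, excess = 1000, m = 3) {
  sys <- rand_panel(seed, m = m)
  sp <- tibble::as_tibble(sys)
  sp$kd <- 0
  sp$c0 <- pmax(sp$c0, excess * sp$n * attr(sys, "N0"))
  corona_system(sp, attr(sys, "N0"))
}

# wide matrix of f values (times x species) from a trajectory
f_matrix <- function(traj, system) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(traj),
                             id_cols = "time",
                             names_from = "species", values_from = "f")
  as.matrix(wide[system$name])
}

traj_times <- function(traj) unique(tibble::as_tibble(traj)$time)
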