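# Small in-code fixtures shared across tests.

# A compact synthetic group: 8x8x2 grid, one planted network, few subjects.
tiny_networks <- function(grid = c(8, 8, 2)) {
  cube <- function(xr, yr, zr) {
    a <- array(FALSE, grid)
    a[xr, yr, zr] <- TRUE
    a
  }
  list(list(mask = cube(1:3, 1:3, 1), conditions = "physical_pain",
            amplitude = 1),
       list(mask = cube(6:8, 6:8, 2), conditions = "affective_control",
            amplitude = 1))
}

tiny_group <- function(n_subjects = 6, seed = 21, ...) {
  spec <- synthetic_spec(grid_dims = c(8, 8, 2), n_subjects = n_subjects,
                         networks = tiny_networks(), seed = seed, ...)
  list(spec = spec, design = default_block_design(),
       group = simulate_group(spec, default_block_design()))
}

# Random phase matrices for sync-map property tests.
random_phases <- function(n_subjects, nv, nt, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_subjects),
         function(i) matrix(stats::runif(nv * nt, -pi, pi), nv, nt))
}
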