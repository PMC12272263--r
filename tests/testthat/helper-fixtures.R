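# Lazily built, session-cached fixtures shared across test files. The
# expensive ones (full species pipeline runs) are built once and reused by
# the qualitative-regression and planted-recovery acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Plain flat lattice sheet (no folds) for small geometric tests.
flat_sheet <- function(nx, ny, spacing = 1) {
  v <- cbind(
    x = rep(seq_len(nx) - 1, times = ny) * spacing,
    y = rep(seq_len(ny) - 1, each = nx) * spacing,
    z = 0
  )
  surface_mesh(v, tmstarget:::lattice_faces(nx, ny))
}

human_run <- function() {
  fixture("human_run", function()
    run_pipeline(run_config("human", seed = 1)))
}

macaque_run <- function() {
  fixture("macaque_run", function()
    run_pipeline(run_config("macaque", seed = 1)))
}
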