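# Shared, lazily built fixtures. Building an SPFD factorization or a lead
# field matrix is the expensive part of most tests, so each is built once
# per test run and cached here.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# -- small phantom (24^3): fast enough for per-module tests ------------------

small_spec <- function() phantom_spec(dims = c(24, 24, 24))

small_model <- function() {
  fixture("small_model", function() make_block_torso(small_spec()))
}

small_electrodes <- function() {
  fixture("small_electrodes", function() phantom_electrodes(small_spec()))
}

small_system <- function() {
  fixture("small_system", function() spfd_system(small_model()))
}

small_factor <- function() {
  fixture("small_factor", function() spfd_factor(small_system()))
}

small_grid <- function() {
  fixture("small_grid", function() select_source_points(small_model(), 6))
}

small_lfm <- function() {
  fixture("small_lfm", function() {
    build_lfm(small_model(), small_electrodes(), small_grid())
  })
}

# -- default phantom (40^3): the study-scale conditions ----------------------

default_spec <- function() phantom_spec()

default_model <- function() {
  fixture("default_model", function() make_block_torso(default_spec()))
}

default_electrodes <- function() {
  fixture("default_electrodes", function() phantom_electrodes(default_spec()))
}

default_lfm <- function() {
  fixture("default_lfm", function() {
    build_lfm(default_model(), default_electrodes(),
              select_source_points(default_model(), 6))
  })
}

# forward-solve an axis-aligned on-grid unit dipole and return the
# electrode potentials (probes the LFM independently of build_lfm)
probe_phi <- function(system, factor, node, axis, electrodes) {
  src <- dipole_source(node, axis)
  fld <- solve_spfd(system, src, method = "direct", factor = factor)
  electrode_potentials(fld, electrodes)
}
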