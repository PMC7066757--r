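# Shared fixtures: reduced-size phantoms and fast registration configs for
# unit tests. Acceptance tests use the full defaults.

# small phantom grid that still contains the whole knee geometry
small_spec <- function(...) {
  phantom_spec(dims = c(100, 100, 54), spacing = c(1.5, 1.5, 3), ...)
}

# a cheap affine configuration for unit-level registration checks
fast_affine <- function(...) {
  registration_config("affine", max_iterations = 150L, n_points = 800L,
                      ...)
}

fast_bspline <- function(...) {
  registration_config("bspline", max_iterations = 80L, n_points = 800L,
                      ...)
}

# smooth random test volume
smooth_volume <- function(dims = c(16, 16, 16), seed = 1,
                          spacing = c(1, 1, 1), modality = "CT") {
  arr <- with_seed_test(seed, array(stats::rnorm(prod(dims)), dims))
  arr <- spectreg:::gaussian_smooth(arr, c(2, 2, 2))
  vol_image(arr, spacing, c(0, 0, 0), modality)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# full landmark set on a simple grid for VOI tests
toy_landmarks <- function() {
  lm <- rbind(FibulaHead = c(30, 60, 90), FTP = c(50, 40, 40),
              FLE = c(10, 50, 60), FME = c(60, 50, 60),
              FKC = c(35, 50, 70), TibiaLateralPeak = c(25, 50, 75),
              TibiaMedialPeak = c(45, 50, 75),
              ProximalMargin = c(35, 20, 50), DistalMargin = c(35, 20, 70),
              LateralMargin = c(25, 20, 60), MedialMargin = c(45, 20, 60))
  landmark_set(lm)
}

toy_image <- function(dims = c(120, 120, 60), spacing = c(0.98, 0.98, 3),
                      value = 0, modality = "CT") {
  vol_image(array(value, dims), spacing, c(0, 0, 0), modality)
}
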