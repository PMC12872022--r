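# shared fixtures, built once per test session

make_blobs <- function(n, d, sep, seed, pos_fraction = 0.5) {
  set.seed(seed)
  y <- rbinom(n, 1, pos_fraction)
  X <- matrix(rnorm(n * d), n, d) + sep * y
  list(X = X, y = y)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a calibrated PET family profile reused across test files
pet_family <- function() {
  cached("pet_family", generate_family(
    family_spec("PET", consensus_length = 100L, n_members = 10L,
                identity_band = c(0.7, 0.9), seed = 41L)))
}

pet_profile <- function() {
  cached("pet_profile", {
    fam <- pet_family()
    calibrate_profile(build_profile(fam$msa, "PET"), n_random = 200L,
                      len_distribution = 80:200, seed = 42L)
  })
}
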