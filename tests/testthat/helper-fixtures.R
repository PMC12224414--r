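# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# full-size synthetic norms + embedding (100 items), the study conditions
fixture_norms <- function() cached("norms", function() simulate_feature_norms(seed = 7))

fixture_rsm <- function() cached("rsm", function() build_cosine_rsm(fixture_norms()))

fixture_embedding <- function() cached("embedding", function() {
  svd_embed(fixture_rsm(), r = 3, domains = fixture_norms()$domains)
})

# small embedding (20 items) for fast decoder tests
fixture_small_embedding <- function() cached("small_embedding", function() {
  norms <- simulate_feature_norms(n_items = 20, n_subcats = 2, seed = 3)
  svd_embed(build_cosine_rsm(norms), r = 3, domains = norms$domains)
})

random_psd_similarity <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  S <- tcrossprod(A)
  d <- sqrt(diag(S))
  S <- S / outer(d, d)
  diag(S) <- 1
  S
}
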