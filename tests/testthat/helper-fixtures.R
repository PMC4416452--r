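# small in-code fixtures shared across tests

# n smooth spectra on the full export grid with known splice distortions
smooth_raw_set <- function(n = 3, seed = 1, grid = 350:2500) {
  set.seed(seed)
  m <- t(sapply(seq_len(n), function(i) {
    0.1 + 0.35 / (1 + exp(-(grid - 710) / 20)) +
      0.02 * sin(grid / (150 + 5 * i))
  }))
  spectra_set(m, grid, sprintf("s%d", seq_len(n)), state = "raw")
}

# metadata matching a spectra_set
toy_records <- function(set, species = "sp1", leaf_type = "young") {
  n <- nrow(set$matrix)
  data.frame(sample_id = set$sample_ids,
             species = rep_len(species, n),
             leaf_type = rep_len(leaf_type, n),
             treatment = 0,
             delta15N = seq_len(n), n_content = 1.5, gwc = 1.2, sla = 8)
}

# low-dimensional regression instance with a planted linear signal
toy_xy <- function(n = 40, p = 8, seed = 1, noise_sd = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("v", seq_len(p))
  beta <- c(2, -1, rep(0, p - 2))
  list(X = X, y = drop(X %*% beta) + rnorm(n, sd = noise_sd), beta = beta)
}

# greenhouse dataset cached per test session (generation is ~0.5 s)
greenhouse_fixture <- local({
  cache <- NULL
  function(seed = 42) {
    if (is.null(cache)) cache <<- generate_greenhouse_dataset(seed = seed)
    cache
  }
})

# one moderately sized end-to-end species run shared across test files
species_run_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gh <- greenhouse_fixture()
      cache <<- suppressWarnings(suppressMessages(
        run_species_model(gh$spectra, gh$records, "H. rosa-sinensis",
                          run_config(seed = 21))))
    }
    cache
  }
})
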