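# Shared fixtures, built lazily and cached for the session so expensive
# simulations run once even when several test files use them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small deterministic count matrix with two obvious expression blobs
toy_blobs <- function(n_per = 60, n_genes = 80, seed = 7) {
  set.seed(seed)
  mu <- matrix(1, n_genes, 2)
  mu[1:20, 1] <- 10
  mu[21:40, 2] <- 10
  cols <- cbind(
    matrix(rnbinom(n_genes * n_per, mu = mu[, 1], size = 10), n_genes),
    matrix(rnbinom(n_genes * n_per, mu = mu[, 2], size = 10), n_genes)
  )
  m <- Matrix::Matrix(cols, sparse = TRUE)
  rownames(m) <- sprintf("g%d", seq_len(n_genes))
  colnames(m) <- sprintf("c%d", seq_len(2 * n_per))
  list(counts = as(m, "dMatrix"), cluster = rep(1:2, each = n_per))
}

default_rna_sim <- function() {
  cached("rna_sim", simulate_scrnaseq(n_clusters = 5, n_cells = 2000,
                                      n_genes = 500, doublet_rate = 0.1,
                                      seed = 1))
}

default_rna_run <- function() {
  cached("rna_run", {
    sim <- default_rna_sim()
    detect_doublets(sim$counts, dbr = 0.1, seed = 1)
  })
}

default_atac_sim <- function() {
  cached("atac_sim", simulate_fragments(seed = 3))
}
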