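# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so pipeline stages don't perturb user
# randomness.
with_seed <- function(seed, code) {
  force(seed)  # before snapshotting: the seed expression may itself draw
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

libsizes <- function(counts) Matrix::colSums(counts)

# Coerce a cluster argument (dblkit_clusters object, named/unnamed vector, or
# tibble with droplet_id/cluster columns) to an integer label vector.
cluster_labels <- function(clusters, n = NULL) {
  lab <- if (inherits(clusters, "dblkit_clusters")) clusters$labels
  else if (is.data.frame(clusters)) clusters$cluster
  else clusters
  lab <- as.integer(as.factor(lab))
  if (!is.null(n) && length(lab) != n) {
    abort(sprintf("cluster labels (%d) do not match droplet count (%d)",
                  length(lab), n))
  }
  lab
}
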