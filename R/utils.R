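# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x > 0 && x == round(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so simulation never perturbs user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Connected components of the subgraph of a logical adjacency matrix induced
# by the node indices in `idx`. Plain BFS: this sits in the permutation-test
# hot loop, so no graph-object construction.
connected_components <- function(adj, idx) {
  if (length(idx) == 0L) return(list())
  comps <- list()
  remaining <- idx
  while (length(remaining) > 0L) {
    queue <- remaining[1L]
    remaining <- remaining[-1L]
    comp <- queue
    while (length(queue) > 0L) {
      node <- queue[1L]
      queue <- queue[-1L]
      if (length(remaining) > 0L) {
        nb <- remaining[adj[node, remaining]]
        if (length(nb) > 0L) {
          comp <- c(comp, nb)
          queue <- c(queue, nb)
          remaining <- setdiff(remaining, nb)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}
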