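#' Scalp montage with spatial adjacency
#'
#' A montage names the scalp channels and carries a symmetric, irreflexive
#' adjacency graph over them. The graph defines spatial neighborhood for
#' cluster formation in the permutation test and for bad-channel
#' interpolation. Optional 2-D schematic coordinates (x: left-right in
#' \[-1, 1\], y: posterior-anterior in \[-1, 1\]) are used to build source
#' topographies for the simulator.
#'
#' @param channels character vector of unique channel labels.
#' @param adjacency either a two-column character matrix of unordered channel
#'   pairs, or a logical adjacency matrix with dimnames equal to `channels`.
#' @param coords optional numeric matrix (`length(channels)` x 2) of schematic
#'   positions, rows named by channel.
#' @param check_connected require the adjacency graph to be connected
#'   (default `TRUE`; disable only for deliberately degenerate test graphs).
#' @return an object of class `rift_montage`: a list with elements
#'   `channels`, `adjacency` (logical matrix) and `coords`.
#' @export
rift_montage <- function(channels, adjacency, coords = NULL, check_connected = TRUE) {
  if (!is.character(channels) || anyDuplicated(channels) || length(channels) < 1L) {
    stopf("montage: `channels` must be unique, non-empty labels")
  }
  n <- length(channels)
  if (is.matrix(adjacency) && is.logical(adjacency)) {
    adj <- adjacency
    if (!identical(dim(adj), c(n, n)) ||
        !identical(rownames(adj), channels) || !identical(colnames(adj), channels)) {
      stopf("montage: logical adjacency must be %d x %d with dimnames = channels", n, n)
    }
  } else {
    pairs <- adjacency
    if (is.list(pairs)) pairs <- do.call(rbind, lapply(pairs, as.character))
    if (!is.matrix(pairs) || ncol(pairs) != 2L || !is.character(pairs)) {
      stopf("montage: `adjacency` must be a 2-column matrix of channel pairs")
    }
    unknown <- setdiff(unique(as.vector(pairs)), channels)
    if (length(unknown) > 0L) {
      stopf("montage: adjacency refers to unknown channel(s): %s",
            paste(unknown, collapse = ", "))
    }
    adj <- matrix(FALSE, n, n, dimnames = list(channels, channels))
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1L]; b <- pairs[i, 2L]
      adj[a, b] <- TRUE
      adj[b, a] <- TRUE
    }
  }
  if (any(diag(adj))) stopf("montage: adjacency must be irreflexive (no self-pairs)")
  if (!isTRUE(all(adj == t(adj)))) stopf("montage: adjacency must be symmetric")
  if (check_connected &&
      length(connected_components(adj, seq_len(n))) != 1L) {
    stopf("montage: adjacency graph must be connected")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 2L) {
      stopf("montage: `coords` must be a %d x 2 matrix", n)
    }
    rownames(coords) <- channels
    colnames(coords) <- c("x", "y")
  }
  structure(list(channels = channels, adjacency = adj, coords = coords),
            class = "rift_montage")
}

# Schematic 2-D positions of the default 31-channel 10-20 cap (one row per
# electrode; left mastoid is a reference site, not a scalp channel).
default_montage_coords <- function() {
  pos <- matrix(c(
    -0.28,  0.90,   # Fp1
     0.28,  0.90,   # Fp2
    -0.85,  0.55,   # F7
    -0.45,  0.55,   # F3
     0.00,  0.55,   # Fz
     0.45,  0.55,   # F4
     0.85,  0.55,   # F8
    -0.65,  0.28,   # FC5
    -0.25,  0.28,   # FC1
     0.25,  0.28,   # FC2
     0.65,  0.28,   # FC6
    -1.00,  0.00,   # T7
    -0.50,  0.00,   # C3
     0.00,  0.00,   # Cz
     0.50,  0.00,   # C4
     1.00,  0.00,   # T8
    -0.65, -0.28,   # CP5
    -0.25, -0.28,   # CP1
     0.00, -0.28,   # CPz
     0.25, -0.28,   # CP2
     0.65, -0.28,   # CP6
    -0.85, -0.55,   # P7
    -0.45, -0.55,   # P3
     0.00, -0.55,   # Pz
     0.45, -0.55,   # P4
     0.85, -0.55,   # P8
    -0.75, -0.75,   # PO9
     0.75, -0.75,   # PO10
    -0.30, -0.90,   # O1
     0.00, -0.90,   # Oz
     0.30, -0.90),  # O2
    ncol = 2L, byrow = TRUE)
  rownames(pos) <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                     "FC5", "FC1", "FC2", "FC6",
                     "T7", "C3", "Cz", "C4", "T8",
                     "CP5", "CP1", "CPz", "CP2", "CP6",
                     "P7", "P3", "Pz", "P4", "P8",
                     "PO9", "PO10", "O1", "Oz", "O2")
  colnames(pos) <- c("x", "y")
  pos
}

#' Default 31-channel 10-20 scalp montage
#'
#' Thirty-one scalp electrodes of a standard 32-channel cap (the remaining
#' electrode sits on the left mastoid and serves as reference, so it is not
#' part of the scalp montage). Adjacency links every pair of electrodes whose
#' schematic 2-D distance is below a fixed threshold, which reproduces the
#' usual nearest-neighbor template (4-6 neighbors for interior electrodes,
#' fewer at the rim) and yields a connected graph.
#'
#' @param neighbor_distance distance threshold on the schematic layout
#'   (default 0.58, calibrated once to the layout spacing).
#' @return a [rift_montage] with 31 channels, adjacency and coordinates.
#' @export
default_montage <- function(neighbor_distance = 0.58) {
  pos <- default_montage_coords()
  d <- as.matrix(stats::dist(pos))
  adj <- d > 0 & d < neighbor_distance
  rift_montage(rownames(pos), adj, coords = pos)
}

#' Neighbors of a channel in a montage
#'
#' @param montage a [rift_montage].
#' @param channel a channel label present in the montage.
#' @return character vector of neighboring channel labels (montage order).
#' @export
montage_neighbors <- function(montage, channel) {
  stopifnot(inherits(montage, "rift_montage"))
  if (!channel %in% montage$channels) stopf("unknown channel: %s", channel)
  montage$channels[montage$adjacency[channel, ]]
}

#' @export
print.rift_montage <- function(x, ...) {
  cat(sprintf("<rift_montage> %d channels, %d adjacency pairs\n",
              length(x$channels), sum(x$adjacency) / 2L))
  cat("  ", paste(x$channels, collapse = " "), "\n")
  invisible(x)
}

#' Read / write a montage as JSON
#'
#' The JSON layout is `{"channels": [...], "adjacency": [["F3","Fz"], ...]}`,
#' optionally with a `"coords"` object mapping channels to `[x, y]`.
#'
#' @param path file path.
#' @return `read_montage()` returns a [rift_montage]; `write_montage()`
#'   returns `path` invisibly.
#' @export
read_montage <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$channels)) stopf("montage JSON: missing field 'channels'")
  if (is.null(obj$adjacency)) stopf("montage JSON: missing field 'adjacency'")
  adj <- obj$adjacency
  if (is.data.frame(adj)) adj <- as.matrix(adj)
  coords <- NULL
  if (!is.null(obj$coords)) {
    coords <- do.call(rbind, obj$coords[obj$channels])
  }
  rift_montage(as.character(obj$channels), adj, coords = coords)
}

#' @rdname read_montage
#' @param montage a [rift_montage] to serialize.
#' @export
write_montage <- function(montage, path) {
  stopifnot(inherits(montage, "rift_montage"))
  adj <- montage$adjacency
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  pair_list <- lapply(seq_len(nrow(pairs)), function(i) {
    c(montage$channels[pairs[i, 1L]], montage$channels[pairs[i, 2L]])
  })
  obj <- list(channels = montage$channels, adjacency = pair_list)
  if (!is.null(montage$coords)) {
    obj$coords <- stats::setNames(
      lapply(seq_along(montage$channels), function(i) unname(montage$coords[i, ])),
      montage$channels)
  }
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
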