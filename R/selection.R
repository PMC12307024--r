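pc_slice <- function(pc, freq) {
  stopifnot(inherits(pc, "rift_pc"))
  fi <- match(freq, pc$freqs)
  if (is.na(fi)) stopf("frequency %g Hz is not on the analysis grid", freq)
  pc$pc[, , , fi, drop = FALSE]
}

# Condition-averaged percent change at one frequency:
# participants x channels matrix.
pc_cond_avg <- function(pc, freq) {
  sl <- pc_slice(pc, freq)
  m <- apply(sl, c(1L, 3L), mean)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L, dimnames = dimnames(sl)[c(1L, 3L)])
  m
}

#' Per-participant top-k electrodes at a frequency
#'
#' Selects, for one participant, the `k` electrodes with the largest
#' percentage power change between baseline and tagging window at the
#' target frequency, averaged over the two conditions (so the selection
#' favors neither condition). Ties are broken by montage order.
#'
#' @param pc a `rift_pc` percent-change map.
#' @param participant participant id (dimension name) or index.
#' @param freq target frequency in Hz; must be on the grid.
#' @param k number of electrodes to select (default 6).
#' @return character vector of `k` electrode labels, in descending order of
#'   percent change.
#' @export
top_k_electrodes <- function(pc, participant, freq, k = 6) {
  vals <- pc_cond_avg(pc, freq)
  if (is.character(participant)) {
    participant <- match(participant, rownames(vals))
    if (is.na(participant)) stopf("unknown participant")
  }
  v <- vals[participant, ]
  if (!is_count(k) || k > length(v)) {
    stopf("k must be a positive integer no larger than the channel count")
  }
  ord <- order(-v, seq_along(v))   # montage order breaks ties
  names(v)[ord[seq_len(k)]]
}

#' Largest neighboring cluster within a selected electrode set
#'
#' Computes the connected components of the montage adjacency subgraph
#' induced by the selected electrodes and returns the largest. A size tie is
#' broken in favor of the component containing the electrode with the
#' largest value (when `values` is given), then by montage order. Unlike
#' cluster formation in the permutation test, a singleton component is a
#' valid result here.
#'
#' @param selected character vector of electrode labels.
#' @param montage a [rift_montage].
#' @param values optional named numeric vector (e.g. percent change per
#'   electrode) used for tie-breaking.
#' @return character vector of electrode labels, in montage order.
#' @export
largest_neighbor_cluster <- function(selected, montage, values = NULL) {
  stopifnot(inherits(montage, "rift_montage"))
  if (length(selected) == 0L) stopf("selected electrode set is empty")
  idx <- match(selected, montage$channels)
  if (anyNA(idx)) stopf("unknown electrode(s): %s",
                        paste(selected[is.na(idx)], collapse = ", "))
  comps <- connected_components(montage$adjacency, sort(idx))
  sizes <- lengths(comps)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L && !is.null(values)) {
    peak <- vapply(comps[best], function(c_) max(values[montage$channels[c_]]), 0)
    best <- best[peak == max(peak)]
  }
  if (length(best) > 1L) {
    # montage order: component containing the earliest channel wins
    best <- best[which.min(vapply(comps[best], min, 0L))]
  }
  montage$channels[comps[[best[1L]]]]
}

#' Electrode-selection contrast at the intermodulation frequency
#'
#' Implements the per-participant electrode-selection procedure and the
#' group-level condition contrast: per participant, the top `k` electrodes
#' by condition-averaged percent change at `freq` are reduced to their
#' largest neighboring cluster; the percent change is then averaged over
#' that cluster per condition; finally a two-tailed paired t-test of
#' related minus unrelated is computed across participants, with Cohen's
#' `d = mean(diff) / sd(diff)` (signed; a negative t/d means less power
#' change in the related condition).
#'
#' @param pc a `rift_pc` percent-change map covering both conditions.
#' @param montage a [rift_montage].
#' @param freq target frequency in Hz (on the grid).
#' @param k electrodes to pre-select per participant (default 6).
#' @return an object of class `rift_selection`: `per_participant` data frame
#'   (participant, selected electrodes, cluster electrodes, per-condition
#'   means), group `t`, `df`, `p`, `cohens_d`, `freq`, `k`.
#' @export
selection_contrast <- function(pc, montage, freq, k = 6) {
  stopifnot(inherits(pc, "rift_pc"), inherits(montage, "rift_montage"))
  sl <- pc_slice(pc, freq)
  if (dim(sl)[2L] != 2L || anyNA(sl)) {
    stopf("both conditions must be present for every participant")
  }
  vals <- pc_cond_avg(pc, freq)
  participants <- rownames(vals)
  rows <- lapply(seq_along(participants), function(p) {
    top <- top_k_electrodes(pc, p, freq, k)
    cl <- largest_neighbor_cluster(top, montage, values = vals[p, ])
    data.frame(participant = participants[p],
               selected = paste(top, collapse = ","),
               cluster = paste(cl, collapse = ","),
               mean_related = mean(sl[p, "related", cl, 1L]),
               mean_unrelated = mean(sl[p, "unrelated", cl, 1L]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  d <- tab$mean_related - tab$mean_unrelated
  n <- length(d)
  if (n < 2L) stopf("need at least 2 participants for the group contrast")
  sd_d <- stats::sd(d)
  t <- if (sd_d == 0) 0 else mean(d) / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  cohens_d <- if (sd_d == 0) 0 else mean(d) / sd_d
  structure(list(per_participant = tab, t = t, df = n - 1L, p = p,
                 cohens_d = cohens_d, freq = freq, k = k),
            class = "rift_selection")
}

#' @export
print.rift_selection <- function(x, ...) {
  cat(sprintf("<rift_selection> %g Hz, top-%d selection, %d participants\n",
              x$freq, x$k, nrow(x$per_participant)))
  cat(sprintf("  related - unrelated: t(%d) = %.2f, p = %.4g, Cohen's d = %.2f\n",
              x$df, x$t, x$p, x$cohens_d))
  invisible(x)
}

group_mean_selected_pc <- function(pc, montage, freq, k) {
  sel <- selection_contrast(pc, montage, freq, k)
  mean((sel$per_participant$mean_related +
          sel$per_participant$mean_unrelated) / 2)
}

#' Neighbor-frequency validation of the intermodulation peak
#'
#' Runs the full selection procedure at the intermodulation frequency and
#' its neighbors and compares the group-mean selected percent change. A true
#' intermodulation response is sharply localized in frequency, so the peak
#' should be most pronounced at the intermodulation frequency itself, not at
#' 12/13/15/16 Hz.
#'
#' @param pc a `rift_pc` percent-change map.
#' @param montage a [rift_montage].
#' @param k electrodes to pre-select (default 6).
#' @param freqs frequencies to compare (default 12:16 Hz); all must be on
#'   the grid.
#' @return list with `table` (data frame: frequency_hz, mean_percent_change)
#'   and `peak_frequency` (the argmax).
#' @export
neighbor_frequency_validation <- function(pc, montage, k = 6,
                                          freqs = c(12, 13, 14, 15, 16)) {
  missing <- setdiff(freqs, pc$freqs)
  if (length(missing) > 0L) {
    stopf("frequency grid is missing %s Hz", paste(missing, collapse = ", "))
  }
  means <- vapply(freqs, function(f) group_mean_selected_pc(pc, montage, f, k), 0)
  tab <- data.frame(frequency_hz = freqs, mean_percent_change = means)
  list(table = tab, peak_frequency = freqs[which.max(means)])
}

#' Base-frequency validation of the selection procedure
#'
#' Applies the same per-participant selection at the main tagging
#' frequencies and tabulates, per frequency, how often each electrode
#' appears in the selected clusters across participants. On a sound
#' selection procedure the visual tag frequency should recruit
#' occipital/central electrodes and the auditory tag a broader set.
#'
#' @inheritParams neighbor_frequency_validation
#' @param freqs tagging frequencies to inspect (default 54 and 68 Hz).
#' @return named list (one entry per frequency) of data frames
#'   `electrode`, `count`, in montage order.
#' @export
base_frequency_validation <- function(pc, montage, k = 6, freqs = c(54, 68)) {
  missing <- setdiff(freqs, pc$freqs)
  if (length(missing) > 0L) {
    stopf("frequency grid is missing %s Hz", paste(missing, collapse = ", "))
  }
  out <- lapply(freqs, function(f) {
    sel <- selection_contrast(pc, montage, f, k)
    members <- unlist(strsplit(sel$per_participant$cluster, ","))
    counts <- vapply(montage$channels, function(ch) sum(members == ch), 0L)
    data.frame(electrode = montage$channels, count = counts,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  names(out) <- as.character(freqs)
  out
}

#' Export a selection result as JSON plus a per-participant TSV
#'
#' @param x a `rift_selection`.
#' @param json_path,tsv_path output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
export_selection <- function(x, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(x, "rift_selection"))
  if (!is.null(json_path)) {
    obj <- list(frequency_hz = x$freq, k = x$k, t = x$t, df = x$df, p = x$p,
                cohens_d = x$cohens_d)
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(x$per_participant, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(json = json_path, tsv = tsv_path))
}
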