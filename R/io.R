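#' Write / read an epoch set
#'
#' Native single-file epoch container: the first line is a JSON header
#' (fields `format`, `version`, `n_trials`, `n_channels`, `n_samples`,
#' `sample_rate`, `t0`, `channels`, `condition`, `participant_id`,
#' `montage`), terminated by a newline, followed by the sample payload as
#' IEEE-754 little-endian float64 in R array (column-major) order over
#' `[trial, channel, sample]`. The round trip is lossless; condition labels
#' and the montage (including coordinates when present) survive.
#'
#' @param epochs a `rift_epochs` object.
#' @param path file path (conventionally `.repochs`).
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()`
#'   returns the reconstructed `rift_epochs`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "rift_epochs"))
  d <- dim(epochs$data)
  mon <- epochs$montage
  adj <- mon$adjacency
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  header <- list(
    format = "rifteeg-epochs", version = 1L,
    n_trials = d[1L], n_channels = d[2L], n_samples = d[3L],
    sample_rate = epochs$sample_rate, t0 = epochs$time[1L],
    channels = mon$channels, condition = epochs$condition,
    participant_id = epochs$participant_id,
    montage = list(
      adjacency = lapply(seq_len(nrow(pairs)), function(i) {
        c(mon$channels[pairs[i, 1L]], mon$channels[pairs[i, 2L]])
      }),
      coords = if (is.null(mon$coords)) NULL else
        stats::setNames(lapply(seq_len(nrow(mon$coords)),
                               function(i) unname(mon$coords[i, ])),
                        mon$channels)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(
    jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), "\n")), con)
  writeBin(as.double(epochs$data), con, size = 8L, endian = "little")
  invisible(path)
}

read_header_line <- function(con) {
  bytes <- raw(0)
  repeat {
    chunk <- readBin(con, "raw", n = 4096L)
    if (length(chunk) == 0L) break
    nl <- which(chunk == as.raw(10L))
    if (length(nl) > 0L) {
      bytes <- c(bytes, chunk[seq_len(nl[1L] - 1L)])
      # rewind to just past the newline
      seek(con, seek(con) - (length(chunk) - nl[1L]))
      return(bytes)
    }
    bytes <- c(bytes, chunk)
  }
  stopf("epoch file: no header line found (truncated or not a rifteeg-epochs file)")
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- tryCatch(
    jsonlite::fromJSON(rawToChar(read_header_line(con)), simplifyVector = TRUE),
    error = function(e) stopf("epoch file: malformed JSON header (%s)",
                              conditionMessage(e)))
  for (field in c("format", "n_trials", "n_channels", "n_samples",
                  "sample_rate", "t0", "channels", "condition",
                  "participant_id", "montage")) {
    if (is.null(header[[field]])) stopf("epoch file: missing header field '%s'", field)
  }
  if (!identical(header$format, "rifteeg-epochs")) {
    stopf("epoch file: unexpected format '%s'", header$format)
  }
  bad <- setdiff(unique(header$condition), c("related", "unrelated"))
  if (length(bad) > 0L) {
    stopf("epoch file: unknown condition label(s): %s", paste(bad, collapse = ", "))
  }
  n <- header$n_trials * header$n_channels * header$n_samples
  payload <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(payload) < n) {
    stopf("epoch file: truncated payload (expected %d samples, found %d)",
          n, length(payload))
  }
  adjacency <- header$montage$adjacency
  if (is.null(adjacency)) stopf("epoch file: missing header field 'montage.adjacency'")
  if (is.data.frame(adjacency)) adjacency <- as.matrix(adjacency)
  coords <- NULL
  if (!is.null(header$montage$coords)) {
    coords <- do.call(rbind, header$montage$coords[header$channels])
  }
  montage <- rift_montage(as.character(header$channels), adjacency,
                          coords = coords)
  data <- array(payload, dim = c(header$n_trials, header$n_channels,
                                 header$n_samples))
  dimnames(data) <- list(NULL, montage$channels, NULL)
  time <- header$t0 + (seq_len(header$n_samples) - 1) / header$sample_rate
  new_epoch_set(data, time, header$condition, header$participant_id,
                header$sample_rate, montage)
}

#' Read / write a simulation configuration
#'
#' YAML (`.yaml`/`.yml`) or JSON by file extension. All scalar fields of
#' [sim_config()] are supported plus nested `tag:` fields and explicit
#' `topo_audio`/`topo_visual`/`topo_im` weight vectors; `seed` is mandatory
#' in a config file.
#'
#' @param path config file path.
#' @param montage montage to attach (default [default_montage()]).
#' @return a `rift_sim_config`.
#' @export
read_sim_config <- function(path, montage = default_montage()) {
  obj <- read_config_file(path)
  if (is.null(obj$seed)) stopf("sim config: 'seed' is mandatory")
  tag_args <- obj$tag
  obj$tag <- NULL
  tag <- if (is.null(tag_args)) tag_config() else do.call(tag_config, tag_args)
  for (f in c("topo_audio", "topo_visual", "topo_im")) {
    if (!is.null(obj[[f]])) obj[[f]] <- as.numeric(obj[[f]])
  }
  known <- setdiff(names(formals(sim_config)), c("tag", "montage"))
  unknown <- setdiff(names(obj), known)
  if (length(unknown) > 0L) {
    stopf("sim config: unknown field(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, c(obj, list(tag = tag, montage = montage)))
}

#' @rdname read_sim_config
#' @param cfg a `rift_sim_config` to serialize (topographies and montage are
#'   written alongside the scalars).
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "rift_sim_config"))
  obj <- cfg[setdiff(names(cfg), c("tag", "montage", "topo_alpha"))]
  obj$tag <- unclass(cfg$tag)
  write_config_file(obj, path)
  invisible(path)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

write_config_file <- function(obj, path) {
  if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    # I(17) significant digits: doubles survive the round trip bit-exactly
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  }
  invisible(path)
}
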