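#' Default pipeline configuration
#'
#' Nested list covering every stage: `sim` (arguments of [sim_config()]),
#' `preprocess` (`enabled`, `low`, `high`, `notches`, optional
#' `reference_channels` and `bad_channels`), `spectra` (`f_lo`, `f_hi`,
#' `step`), `cluster` (`n_perm`, `alpha`, `alpha_form`) and `selection`
#' (`k`). Filtering is disabled by default: the generative model contains no
#' line noise or drift, so the filter stage is an identity up to edge
#' effects; enable it when adding such components.
#'
#' @param seed integer master seed; the simulation uses it directly and each
#'   permutation stage derives a distinct fixed offset from it.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(seed = as.integer(seed),
       sim = list(seed = as.integer(seed)),
       preprocess = list(enabled = FALSE, low = 0.1, high = 100,
                         notches = c(50, 100, 150)),
       spectra = list(f_lo = 1, f_hi = 80, step = 1),
       cluster = list(n_perm = 5000, alpha = 0.05, alpha_form = 0.05),
       selection = list(k = 6))
}

#' Read a pipeline configuration file
#'
#' YAML or JSON (by extension), merged over [default_pipeline_config()];
#' `seed` is mandatory.
#'
#' @param path config file path.
#' @return nested configuration list.
#' @export
read_pipeline_config <- function(path) {
  obj <- read_config_file(path)
  if (is.null(obj$seed)) stopf("pipeline config: 'seed' is mandatory")
  base <- default_pipeline_config(obj$seed)
  for (section in names(base)) {
    if (section %in% names(obj) && is.list(base[[section]])) {
      for (key in names(obj[[section]])) {
        base[[section]][[key]] <- obj[[section]][[key]]
      }
    } else if (section %in% names(obj)) {
      base[[section]] <- obj[[section]]
    }
  }
  extra <- setdiff(names(obj), names(base))
  if (length(extra) > 0L) {
    stopf("pipeline config: unknown section(s): %s", paste(extra, collapse = ", "))
  }
  base
}

power_matrix <- function(spectra, freq, combine_conditions = TRUE) {
  fi <- match(freq, spectra$freqs)
  if (is.na(fi)) stopf("frequency %g Hz is not on the analysis grid", freq)
  sl <- spectra$power[, , , fi, drop = FALSE]
  if (combine_conditions) {
    m <- apply(sl, c(1L, 3L), mean)
  } else {
    m <- sl
  }
  m
}

pc_condition_matrix <- function(pc, freq, condition) {
  fi <- match(freq, pc$freqs)
  if (is.na(fi)) stopf("frequency %g Hz is not on the analysis grid", freq)
  sl <- pc$pc[, condition, , fi, drop = FALSE]
  matrix(sl, nrow = dim(sl)[1L],
         dimnames = list(dimnames(sl)[[1L]], dimnames(sl)[[3L]]))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full frequency-tagging analysis pipeline
#'
#' Executes the stages in analysis order on a simulated dataset: simulate,
#' optionally preprocess, compute baseline and tagging spectra, run
#' tagging-vs-baseline cluster permutation tests (conditions combined) at
#' the two tag frequencies and the difference intermodulation frequency,
#' compute the percent-change map, and then -- only for frequencies whose
#' tagging-vs-baseline test was significant (the gating rule) -- the
#' between-condition contrasts: cluster tests at the base frequencies and
#' the electrode-selection contrast at the intermodulation frequency.
#' Finally both validation procedures are run. Every statistic is
#' reproducible from the configuration and seed alone.
#'
#' @param config a configuration list ([default_pipeline_config()]), or a
#'   path to a YAML/JSON configuration file.
#' @param out_dir optional output directory; when given, all artifacts
#'   (report JSON, spectra and percent-change TSVs, cluster JSONs, selection
#'   TSV, manifest) are written there.
#' @return an object of class `rift_report`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- config$seed
  if (is.null(seed)) stopf("pipeline config: 'seed' is mandatory")

  cfg <- stage("simulate", {
    sim_args <- config$sim
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    if (!is.null(sim_args$tag)) sim_args$tag <- do.call(tag_config, sim_args$tag)
    do.call(sim_config, sim_args)
  })
  dataset <- stage("simulate", simulate_dataset(cfg))

  if (isTRUE(config$preprocess$enabled)) {
    dataset <- stage("preprocess", {
      pp <- config$preprocess
      out <- lapply(dataset, function(ep) {
        ep <- bandpass_notch(ep, low = pp$low, high = pp$high,
                             notches = pp$notches)
        if (!is.null(pp$reference_channels)) {
          ep <- rereference(ep, pp$reference_channels)
        }
        for (bad in pp$bad_channels) ep <- interpolate_channel(ep, bad)
        ep
      })
      attributes(out) <- attributes(dataset)
      out
    })
  }

  sp <- config$spectra
  tagging <- stage("spectra", windowed_power(dataset, "tagging",
                                             sp$f_lo, sp$f_hi, sp$step))
  baseline <- stage("spectra", windowed_power(dataset, "baseline",
                                              sp$f_lo, sp$f_hi, sp$step))
  pc <- stage("spectra", percent_change(tagging, baseline))

  f_audio <- cfg$tag$f_audio
  f_visual <- cfg$tag$f_visual
  f_im <- intermodulation_freqs(min(f_audio, f_visual),
                                max(f_audio, f_visual))$difference
  cl_cfg <- config$cluster
  montage <- cfg$montage

  vs_baseline <- list()
  freqs_tested <- c(audio = f_audio, visual = f_visual, im = f_im)
  for (i in seq_along(freqs_tested)) {
    f <- freqs_tested[[i]]
    vs_baseline[[names(freqs_tested)[i]]] <- stage("cluster-baseline", cluster_test(
      power_matrix(tagging, f), power_matrix(baseline, f), montage,
      n_perm = cl_cfg$n_perm, alpha = cl_cfg$alpha,
      alpha_form = cl_cfg$alpha_form, seed = (seed + 101L * i) %% .Machine$integer.max))
  }

  condition_tests <- list()
  for (nm in c("audio", "visual")) {
    f <- freqs_tested[[nm]]
    if (any_significant(vs_baseline[[nm]])) {
      condition_tests[[nm]] <- stage("cluster-condition", cluster_test(
        pc_condition_matrix(pc, f, "related"),
        pc_condition_matrix(pc, f, "unrelated"), montage,
        n_perm = cl_cfg$n_perm, alpha = cl_cfg$alpha,
        alpha_form = cl_cfg$alpha_form,
        seed = (seed + 211L * match(nm, c("audio", "visual"))) %% .Machine$integer.max))
    } else {
      condition_tests[nm] <- list(NULL)   # gated out: baseline contrast not significant
    }
  }

  selection <- if (any_significant(vs_baseline$im)) {
    stage("selection", selection_contrast(pc, montage, f_im,
                                          k = config$selection$k))
  } else NULL

  validation_neighbors <- stage("validate-neighbors",
    neighbor_frequency_validation(pc, montage, k = config$selection$k,
                                  freqs = f_im + c(-2, -1, 0, 1, 2)))
  validation_base <- stage("validate-base",
    base_frequency_validation(pc, montage, k = config$selection$k,
                              freqs = c(f_audio, f_visual)))

  report <- structure(list(
    config = config, seed = seed,
    frequencies = list(audio = f_audio, visual = f_visual, im = f_im),
    vs_baseline = vs_baseline,
    condition_tests = condition_tests,
    selection = selection,
    validation_neighbors = validation_neighbors,
    validation_base = validation_base,
    percent_change = pc,
    spectra = list(tagging = tagging, baseline = baseline),
    version = as.character(utils::packageVersion("rifteeg"))),
    class = "rift_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.rift_report <- function(x, ...) {
  cat(sprintf("<rift_report> seed %d, rifteeg %s\n", x$seed, x$version))
  for (nm in names(x$vs_baseline)) {
    ct <- x$vs_baseline[[nm]]
    cat(sprintf("  %s (%g Hz) tagging vs baseline: %s\n", nm,
                x$frequencies[[nm]],
                if (any_significant(ct)) {
                  sprintf("significant (min p = %.4g, %d cluster(s))",
                          min(vapply(ct$clusters, `[[`, 0, "p")),
                          length(ct$clusters))
                } else "not significant"))
  }
  for (nm in names(x$condition_tests)) {
    ct <- x$condition_tests[[nm]]
    cat(sprintf("  %s condition contrast: %s\n", nm,
                if (is.null(ct)) "gated out (baseline contrast not significant)"
                else if (any_significant(ct)) "significant" else "not significant"))
  }
  if (is.null(x$selection)) {
    cat("  selection contrast: gated out\n")
  } else {
    cat(sprintf("  selection contrast at %g Hz: t(%d) = %.2f, p = %.4g, d = %.2f\n",
                x$selection$freq, x$selection$df, x$selection$t,
                x$selection$p, x$selection$cohens_d))
  }
  cat(sprintf("  neighbor-frequency validation peak: %g Hz\n",
              x$validation_neighbors$peak_frequency))
  invisible(x)
}

report_summary_list <- function(x) {
  list(
    seed = x$seed, version = x$version, frequencies = x$frequencies,
    vs_baseline = lapply(x$vs_baseline, function(ct) {
      list(significant = any_significant(ct),
           clusters = lapply(ct$clusters, function(cl) {
             list(electrodes = cl$electrodes, sign = cl$sign,
                  mass = cl$mass, p = cl$p)
           }),
           n_permutations = ct$n_perm)
    }),
    condition_tests = lapply(x$condition_tests, function(ct) {
      if (is.null(ct)) return(list(gated_out = TRUE))
      list(significant = any_significant(ct),
           clusters = lapply(ct$clusters, function(cl) {
             list(electrodes = cl$electrodes, sign = cl$sign,
                  mass = cl$mass, p = cl$p)
           }),
           n_permutations = ct$n_perm)
    }),
    selection = if (is.null(x$selection)) list(gated_out = TRUE) else {
      list(frequency_hz = x$selection$freq, k = x$selection$k,
           t = x$selection$t, df = x$selection$df, p = x$selection$p,
           cohens_d = x$selection$cohens_d)
    },
    validation_neighbors = x$validation_neighbors,
    validation_base = x$validation_base)
}

#' Write a pipeline report bundle to a directory
#'
#' Writes `report.json` (summary statistics), long-format TSVs for spectra
#' and percent change, per-test cluster JSONs, the per-participant selection
#' TSV and a `manifest.json` listing every artifact with the configuration
#' hash. Output is deterministic: identical configurations produce
#' byte-identical bundles.
#'
#' @param report a `rift_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "rift_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(fname, fn) {
    path <- file.path(out_dir, fname)
    fn(path)
    files <<- c(files, fname)
  }
  wr("report.json", function(p) {
    jsonlite::write_json(report_summary_list(report), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })
  wr("percent_change.tsv", function(p) export_spectra_tsv(report$percent_change, p))
  wr("spectra_tagging.tsv", function(p) export_spectra_tsv(report$spectra$tagging, p))
  wr("spectra_baseline.tsv", function(p) export_spectra_tsv(report$spectra$baseline, p))
  for (nm in names(report$vs_baseline)) {
    local({
      nm_ <- nm
      wr(sprintf("cluster_vs_baseline_%s.json", nm_), function(p) {
        export_cluster_json(report$vs_baseline[[nm_]], p,
                            frequency_hz = report$frequencies[[nm_]],
                            contrast = "tagging_vs_baseline",
                            seed = report$seed)
      })
    })
  }
  for (nm in names(report$condition_tests)) {
    if (!is.null(report$condition_tests[[nm]])) {
      local({
        nm_ <- nm
        wr(sprintf("cluster_condition_%s.json", nm_), function(p) {
          export_cluster_json(report$condition_tests[[nm_]], p,
                              frequency_hz = report$frequencies[[nm_]],
                              contrast = "related_vs_unrelated",
                              seed = report$seed)
        })
      })
    }
  }
  if (!is.null(report$selection)) {
    wr("selection.json", function(p) export_selection(report$selection, json_path = p))
    wr("selection_participants.tsv",
       function(p) export_selection(report$selection, tsv_path = p))
  }
  cfg_json <- jsonlite::toJSON(report$config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  manifest <- list(config = report$config, config_md5 = cfg_hash,
                   files = sort(files), version = report$version)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
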