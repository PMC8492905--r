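# End-to-end orchestration: cohort (synthetic or image directory) ->
# per-eye D_box -> quality filter -> group comparisons and correlations ->
# report files. Fully deterministic given the configuration seed.

#' Default pipeline configuration
#'
#' Returns the full configuration template as a nested list; values loaded
#' from a YAML file (or supplied programmatically) override these defaults.
#'
#' @return Named list with blocks `mode` (`"synthetic"` or `"images"`),
#'   `seed`, `out_dir`, `cohort` (arguments of [cohort_sim_config()]),
#'   `with_images`, `image` (arguments of [synth_vasc_params()]), `images`
#'   (directory + metadata CSV for real data), `segmentation`
#'   ([segmentation_params()] arguments), `annulus`, `fd` and `quality`.
#' @export
default_pipeline_config <- function() {
  list(mode = "synthetic", seed = 1L, out_dir = NULL,
       cohort = list(), with_images = FALSE, image = list(),
       images = list(dir = NULL, metadata = NULL),
       segmentation = list(),
       annulus = list(inner_diameter_mm = 0.6, outer_diameter_mm = 2.5),
       fd = list(use_skeleton = TRUE, box_sizes_px = NULL, exclude_faz = TRUE),
       quality = list(threshold = 6))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [default_pipeline_config()].
#' @return The merged configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_pipeline_config(), user)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Builds the cohort, obtains a per-eye-per-layer D_box (from images when
#' available, otherwise from the simulated ground truth), applies the
#' signal-quality filter, and computes all pairwise group comparisons (GEE
#' with inter-eye clustering) and clinical correlations per layer.
#'
#' @param config nested list as from [read_pipeline_config()] /
#'   [default_pipeline_config()], or a path to a YAML file.
#' @return A list of class `analysis_report`: `per_eye` (data frame),
#'   `comparisons`, `correlations`, `qc`, `provenance`. When
#'   `config$out_dir` is set the tables are also written there
#'   (`per_eye.csv`, `comparisons.csv`, `correlations.csv`, `report.json`).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- merge_config(default_pipeline_config(), config)
  seed <- as.integer(config$seed)

  if (config$mode == "synthetic") {
    cc <- do.call(cohort_sim_config, c(config$cohort, list(seed = seed)))
    cohort <- generate_cohort(cc, emit_images = isTRUE(config$with_images),
                              image_params = do.call(synth_vasc_params,
                                                     config$image))
    images <- attr(cohort, "images")
  } else if (config$mode == "images") {
    if (is.null(config$images$metadata)) stop("images mode needs a metadata CSV")
    cohort <- read_cohort_csv(config$images$metadata)
    images <- NULL
  } else stop("unknown mode: ", config$mode)

  seg_p <- do.call(segmentation_params, config$segmentation)
  per_eye <- as.data.frame(cohort)
  qc <- data.frame()

  measure_one <- function(x, key) {
    res <- tryCatch(compute_dbox(
      x, seg_params = seg_p,
      inner_diameter_mm = config$annulus$inner_diameter_mm,
      outer_diameter_mm = config$annulus$outer_diameter_mm,
      exclude_faz = isTRUE(config$fd$exclude_faz),
      use_skeleton = isTRUE(config$fd$use_skeleton),
      box_sizes_px = config$fd$box_sizes_px),
      error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(key = key, dbox = NA_real_, r_squared = NA_real_,
                        faz_found = NA, flags = conditionMessage(res)))
    faz <- attr(res, "intermediates")$faz
    data.frame(key = key, dbox = res$dbox, r_squared = res$r_squared,
               faz_found = !is.null(faz) && isTRUE(faz$found),
               flags = paste(res$flag, collapse = ";"))
  }

  if (config$mode == "synthetic" && !isTRUE(config$with_images)) {
    # cohort-only mode: the simulated ground-truth D_box plays the role of
    # the measured value
    per_eye$dbox <- per_eye$dbox_true
  } else {
    keys <- sprintf("%s_%s_%s", per_eye$subject_id, per_eye$eye, per_eye$layer)
    rows <- lapply(seq_len(nrow(per_eye)), function(i) {
      x <- if (!is.null(images)) images[[keys[i]]]$image
           else {
             f <- file.path(config$images$dir, per_eye$file[i])
             if (!file.exists(f)) stop("missing image file: ", f)
             read_angiogram_png(f, layer = per_eye$layer[i])
           }
      measure_one(x, keys[i])
    })
    qc <- do.call(rbind, rows)
    per_eye$dbox <- qc$dbox
    dropped <- sum(is.na(per_eye$dbox))
    per_eye <- per_eye[!is.na(per_eye$dbox), , drop = FALSE]
    attr(qc, "dropped") <- dropped
  }

  class(per_eye) <- c("cohort_table", "data.frame")
  filt <- quality_filter(per_eye, config$quality$threshold)
  removed <- attr(filt, "removed")

  layers <- intersect(c("SCP", "DCP", "WCP"), unique(filt$layer))
  comparisons <- do.call(rbind, lapply(layers, function(l)
    gee_compare(filt, outcome = "dbox", layer = l)))

  correlations <- do.call(rbind, lapply(layers, function(l) {
    lt <- filt[filt$layer == l, , drop = FALSE]
    class(lt) <- c("cohort_table", "data.frame")
    is_pat <- lt$group == "NMOSD"
    cls <- eye_class(lt)
    one <- function(xc, yc, sub, label) {
      res <- tryCatch(correlate(lt, xc, yc, unit = "subject", subset = sub),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(layer = l, x = xc, y = yc, subgroup = label, r = res$r,
                 n = res$n, p_value = res$p_value, stringsAsFactors = FALSE)
    }
    rbind(one("edss", "dbox", is_pat, "NMOSD"),
          one("edss", "dbox", cls == "NMOSD_NON", "NMOSD_NON"),
          one("edss", "dbox", cls == "NMOSD_ON", "NMOSD_ON"),
          one("va_logmar", "dbox", !is_pat, "HC"),
          one("va_logmar", "dbox", is_pat, "NMOSD"))
  }))

  report <- structure(list(
    per_eye = filt, comparisons = comparisons, correlations = correlations,
    qc = qc,
    provenance = list(config = config, seed = seed,
                      package_version = as.character(utils::packageVersion("octafd")),
                      n_rows_quality_removed = removed$rows,
                      subjects_excluded = removed$subjects)),
    class = "analysis_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write an analysis report to disk
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(report$per_eye),
                   file.path(out_dir, "per_eye.csv"), row.names = FALSE, na = "")
  utils::write.csv(report$comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(report$correlations, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(
    list(provenance = report$provenance[setdiff(names(report$provenance), "config")],
         comparisons = report$comparisons, correlations = report$correlations),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = 10, pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d eye-layer rows, %d comparisons, %d correlations\n",
              nrow(x$per_eye), nrow(x$comparisons),
              if (is.null(x$correlations)) 0L else nrow(x$correlations)))
  invisible(x)
}
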