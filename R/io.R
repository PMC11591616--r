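#' File formats and the pipeline driver
#'
#' Plain delimited text for ERP matrices and montages plus structured JSON
#' sidecars and results, and a configuration-driven end-to-end runner. All
#' times in output files are milliseconds relative to stimulus onset;
#' windows are half-open `[start, end)`.
#'
#' @name cli_io
NULL

#' Write / read an evoked ERP as delimited text with a JSON sidecar
#'
#' The matrix file is tab-separated with a header row of channel labels and
#' one row per time sample; the sidecar carries sampling rate, epoch
#' origin, design labels and units.
#'
#' @param erp an `evoked_erp`.
#' @param path matrix file path (`.tsv`).
#' @param sidecar_path metadata path; defaults to `path` with `.json`
#'   appended.
#' @return `write_erp_matrix` returns the paths invisibly;
#'   `read_erp_matrix` returns an `evoked_erp`.
#' @export
write_erp_matrix <- function(erp, path, sidecar_path = paste0(path, ".json")) {
  stopifnot(inherits(erp, "evoked_erp"))
  m <- t(erp$data)
  colnames(m) <- if (!is.null(rownames(erp$data))) rownames(erp$data) else
    sprintf("E%03d", seq_len(nrow(erp$data)))
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(sfreq = erp$sfreq, t0_ms = erp$t0_ms,
               subject_id = erp$subject_id, language = erp$language,
               embodiment = erp$embodiment, units = "uV",
               n_channels = nrow(erp$data), n_samples = ncol(erp$data))
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar_path))
}

#' @rdname write_erp_matrix
#' @param montage optional `montage` to validate channel labels against.
#' @export
read_erp_matrix <- function(path, sidecar_path = paste0(path, ".json"),
                            montage = NULL) {
  if (!file.exists(sidecar_path)) {
    stop("missing sidecar metadata file: ", sidecar_path)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  needed <- c("sfreq", "t0_ms", "subject_id", "language", "embodiment",
              "units")
  miss <- setdiff(needed, names(meta))
  if (length(miss)) {
    stop("sidecar is missing required key(s): ", paste(miss, collapse = ", "))
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(tab)), nrow(tab), ncol(tab)))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row %d, column '%s' of %s",
                 bad[1L], colnames(tab)[bad[2L]], path))
  }
  if (!is.null(montage)) {
    if (!identical(colnames(tab), montage$labels)) {
      stop("matrix header does not match the montage channel labels")
    }
  }
  scale <- switch(meta$units, uV = 1, "µV" = 1, mV = 1e3, V = 1e6,
                  stop("unknown units in sidecar: ", meta$units))
  evoked_erp(t(m) * scale, meta$sfreq, meta$t0_ms,
             subject_id = meta$subject_id, language = meta$language,
             embodiment = meta$embodiment, channel_names = colnames(tab))
}

#' Read / write a montage as whitespace-delimited text
#'
#' One line per electrode: `label x y z`. Positions off the unit sphere by
#' more than 1e-3 are renormalized with a warning.
#'
#' @param path file path.
#' @return a `montage`.
#' @export
read_montage <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names =
                             c("label", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  if (nrow(tab) < 8L) stop("montage must have at least 8 channels")
  if (anyDuplicated(tab$label)) {
    stop("duplicate channel label in montage file: ",
         tab$label[duplicated(tab$label)][1L])
  }
  pos <- as.matrix(tab[, c("x", "y", "z")])
  nrm <- sqrt(rowSums(pos^2))
  if (any(nrm <= 0)) stop("zero-norm electrode position")
  if (any(abs(nrm - 1) > 1e-3)) {
    warning("montage positions renormalized to the unit sphere")
  }
  montage(tab$label, pos / nrm)
}

#' @rdname read_montage
#' @param mont a `montage`.
#' @export
write_montage <- function(mont, path) {
  tab <- data.frame(label = mont$labels,
                    x = mont$positions[, 1L],
                    y = mont$positions[, 2L],
                    z = mont$positions[, 3L])
  utils::write.table(format(tab, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize a segmentation result to JSON
#'
#' Templates are written as channel-ordered number lists; labels as
#' run-length-encoded spans in ms per condition.
#'
#' @param seg a `microstate_segmentation`.
#' @param path output path.
#' @export
write_segmentation_json <- function(seg, path) {
  spans <- lapply(names(seg$map_windows), function(cn) {
    w <- seg$map_windows[[cn]]
    lapply(seq_len(nrow(w)), function(i) {
      list(map_id = w$map_id[i], t_start_ms = w$t_start_ms[i],
           t_end_ms = w$t_end_ms[i])
    })
  })
  names(spans) <- names(seg$map_windows)
  obj <- list(
    selected_k = seg$selected_k,
    gev_total = seg$gev$after_constraint$total,
    gev_per_map = seg$gev$after_constraint$per_map,
    templates = lapply(seq_len(ncol(seg$templates)),
                       function(m) unname(seg$templates[, m])),
    map_windows = spans,
    params = list(k_max = seg$params$k_max,
                  min_segment_ms = seg$params$min_segment_ms,
                  analysis_window_ms = seg$params$analysis_window_ms,
                  criteria = seg$params$criteria))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.default_config <- function() {
  list(
    stages = c("simulate", "segment", "backfit", "anova"),
    seed = 1L,
    out_dir = ".",
    simulate = list(n_subjects = 29L, n_channels = 128L, sfreq = 1024,
                    subject_sd = 0.2, rho = 0.5, noise_sd = 0.5),
    segmentation = list(k_max = 20L, min_segment_ms = 10,
                        analysis_window_ms = c(0, 700),
                        criteria = c("cv", "kl", "dispersion", "silhouette"),
                        k_fixed = NULL),
    input_dir = NULL,
    log_level = "info")
}

.read_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  def <- .default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in c("simulate", "segmentation")) {
    if (!is.null(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(bad)) {
        stop(sprintf("unknown config key(s) in '%s': %s", sec,
                     paste(bad, collapse = ", ")))
      }
      def[[sec]][names(config[[sec]])] <- config[[sec]]
    }
  }
  for (key in setdiff(names(config), c("simulate", "segmentation"))) {
    def[[key]] <- config[[key]]
  }
  def
}

#' Run the configured analysis pipeline end to end
#'
#' Executes the configured stages (simulate, segment, backfit, anova) and
#' writes all artifacts to the output directory: the fully resolved
#' configuration, the segmentation JSON, tidy back-fit and ANOVA tables,
#' and a structured log with stage timings.
#'
#' @param config a config list, or the path of a JSON/YAML config file.
#'   Unknown keys are rejected. See the package vignette for the schema.
#' @return invisibly, a list with the analysis result and artifact paths.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- .read_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                    stage, sprintf(fmt, ...))
    if (identical(cfg$log_level, "info")) message(line)
    log_lines <<- c(log_lines, line)
  }
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    say(stage, "done in %.2f s", proc.time()[["elapsed"]] - t0)
    out
  }

  dataset <- NULL
  if ("simulate" %in% cfg$stages) {
    dataset <- timed("simulate", {
      sc <- do.call(synth_config, c(list(seed = cfg$seed), cfg$simulate))
      simulate_dataset(sc)
    })
  } else {
    if (is.null(cfg$input_dir)) stop("stage 'load' failed: no input_dir given")
    dataset <- timed("load", {
      files <- sort(list.files(cfg$input_dir, pattern = "\\.tsv$",
                               full.names = TRUE))
      if (!length(files)) stop("no .tsv ERP matrices in input_dir")
      lapply(files, read_erp_matrix)
    })
  }

  sp <- do.call(segmentation_params,
                cfg$segmentation[setdiff(names(cfg$segmentation), "k_fixed")])
  res <- timed("segment+backfit+anova", {
    run_full_analysis(dataset, sp, k_fixed = cfg$segmentation$k_fixed)
  })

  paths <- list(
    config = file.path(cfg$out_dir, "resolved_config.json"),
    segmentation = file.path(cfg$out_dir, "segmentation.json"),
    backfit = file.path(cfg$out_dir, "backfit.tsv"),
    anova = file.path(cfg$out_dir, "anova.tsv"),
    log = file.path(cfg$out_dir, "run_log.txt"))
  resolved <- cfg
  resolved$package_version <- as.character(utils::packageVersion("erpmicro"))
  jsonlite::write_json(resolved, paths$config, auto_unbox = TRUE,
                       digits = NA, null = "null")
  write_segmentation_json(res$segmentation, paths$segmentation)
  utils::write.table(res$backfit, paths$backfit, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$anova, paths$anova, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(log_lines, paths$log)
  say("pipeline", "all artifacts written to %s", cfg$out_dir)
  invisible(list(result = res, paths = paths))
}
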