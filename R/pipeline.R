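# Structured, append-only run log. Events are JSON lines so the log is
# machine-parseable; order of appends is the stage order.
new_run_log <- function(path = NULL) {
  env <- new.env(parent = emptyenv())
  env$events <- list()
  env$path <- path
  structure(env, class = "RunLog")
}

#' Append a structured event to a run log
#'
#' Records a per-stage event (start/end, parameters, counts) in an
#' append-only, machine-parseable log. Each event is one JSON object; if
#' the log was created with a file path, events are also appended to that
#' file as JSON lines.
#'
#' @param log a `RunLog` (created internally by [run_end_to_end()], or via
#'   `blinkcount:::new_run_log()` for standalone use).
#' @param stage stage name (e.g. `"filter"`, `"detect"`).
#' @param event event name (e.g. `"start"`, `"end"`, `"error"`).
#' @param ... named scalar fields to record (parameters, counts).
#' @return The log, invisibly.
#' @export
log_event <- function(log, stage, event, ...) {
  stopifnot(inherits(log, "RunLog"))
  entry <- c(list(seq = length(log$events) + 1L,
                  stage = stage, event = event), list(...))
  log$events[[length(log$events) + 1L]] <- entry
  if (!is.null(log$path)) {
    line <- jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA)
    cat(line, "\n", sep = "", file = log$path, append = TRUE)
  }
  invisible(log)
}

#' @export
print.RunLog <- function(x, ...) {
  cat(sprintf("RunLog: %d event(s)\n", length(x$events)))
  for (e in x$events)
    cat(sprintf("  [%d] %s/%s\n", e$seq, e$stage, e$event))
  invisible(x)
}

#' Read and validate a run manifest
#'
#' A manifest describes one end-to-end run: the movies (path, label,
#' concentration in pg/mL, optional pixel size and exposure), the filter
#' kernel and boundary rule, the candidate thresholds (explicit list or a
#' `start:stop:step` range string), the output directory, and the seed
#' used for any stochastic step. Validation reports *all* problems at
#' once, not one at a time.
#'
#' @param manifest a YAML file path, or an equivalent named list.
#' @return The validated manifest as a list with a normalised `taus`
#'   numeric vector and a `FilterParams` object under `$filter`.
#' @export
read_manifest <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1L) {
    if (!file.exists(manifest))
      bc_stop("missing_file", paste0("manifest not found: ", manifest))
    manifest <- yaml::read_yaml(manifest)
  }
  if (!is.list(manifest))
    bc_stop("bad_manifest", "manifest must be a YAML file or a list")
  problems <- character(0)
  movies <- manifest$movies
  if (is.null(movies) || length(movies) == 0L) {
    problems <- c(problems, "movies: empty movie list")
  } else {
    for (i in seq_along(movies)) {
      m <- movies[[i]]
      if (is.null(m$path) && !inherits(m$stack, "ImageStack"))
        problems <- c(problems, sprintf("movies[%d]: missing path", i))
      else if (!is.null(m$path) && !file.exists(m$path))
        problems <- c(problems, sprintf("movies[%d]: path does not exist: %s",
                                        i, m$path))
      if (is.null(m$label))
        problems <- c(problems, sprintf("movies[%d]: missing label", i))
      cc <- m$concentration
      if (is.null(cc) || !is.numeric(cc) || length(cc) != 1L ||
          !is.finite(cc) || cc <= 0)
        problems <- c(problems,
                      sprintf("movies[%d]: concentration must be > 0 pg/mL", i))
    }
  }
  taus <- parse_taus(manifest$taus)
  if (length(taus) == 0L)
    problems <- c(problems, "taus: non-empty threshold list required")
  filt <- tryCatch({
    if (is.null(manifest$filter)) filter_params()
    else filter_params(kernel = manifest$filter$kernel %||% c(1L, 3L, 3L),
                       boundary = manifest$filter$boundary %||% "reflect")
  }, error = function(e) { problems <<- c(problems, conditionMessage(e)); NULL })
  if (is.null(manifest$output_dir))
    problems <- c(problems, "output_dir: required")
  if (length(problems) > 0L)
    bc_stop("bad_manifest",
            paste0("manifest validation failed:\n  - ",
                   paste(problems, collapse = "\n  - ")))
  manifest$taus <- taus
  manifest$filter <- filt
  manifest$seed <- manifest$seed %||% 1L
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Thresholds as an explicit numeric vector or a "start:stop:step" string.
parse_taus <- function(taus) {
  if (is.null(taus)) return(numeric(0))
  if (is.numeric(taus)) return(sort(unique(as.numeric(taus))))
  if (is.character(taus) && length(taus) == 1L && grepl(":", taus)) {
    parts <- as.numeric(strsplit(taus, ":", fixed = TRUE)[[1]])
    if (length(parts) == 2L) parts <- c(parts, 1)
    if (length(parts) != 3L || any(!is.finite(parts)) || parts[3] <= 0)
      bc_stop("bad_taus", "threshold range must be start:stop:step")
    return(seq(parts[1], parts[2], by = parts[3]))
  }
  suppressWarnings(out <- as.numeric(taus))
  if (any(is.na(out))) bc_stop("bad_taus", "could not parse taus")
  sort(unique(out))
}

# Deterministic md5 of the manifest's parameter content (paths, labels,
# concentrations, kernel, taus, seed) for provenance stamping.
manifest_hash <- function(manifest) {
  keep <- list(
    movies = lapply(manifest$movies, function(m)
      list(path = m$path %||% "<in-memory>", label = m$label,
           concentration = m$concentration)),
    kernel = manifest$filter$kernel,
    boundary = manifest$filter$boundary,
    taus = manifest$taus,
    seed = manifest$seed
  )
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(keep, auto_unbox = TRUE,
                                           digits = NA)), tf)
  unname(tools::md5sum(tf))
}

#' Run the full counting workflow from a manifest
#'
#' End-to-end orchestration: load every movie, filter once, screen all
#' candidate thresholds ([sweep_thresholds()]), pick the operating
#' threshold ([select_threshold()]), and fit the log-concentration
#' calibration at that threshold ([fit_log_linear()]). Writes to
#' `output_dir`:
#'
#' * `sweep.csv` — label, concentration_pg_per_ml, tau, count;
#' * `fit.json` — the selected threshold, calibration fit, software
#'   version, manifest hash and all parameters;
#' * `masks/<label>_mask.tif` — per-movie detection mask at the selected
#'   threshold (8-bit, 0/255);
#' * `summary.txt` — human-readable recap;
#' * `run_log.jsonl` — the structured stage log.
#'
#' Outputs are deterministic: rerunning the same manifest (and seed)
#' reproduces byte-identical CSV/JSON files. Frame indices and pixel
#' coordinates in all outputs are 1-based with origin at the top-left.
#'
#' @param manifest a YAML path or list accepted by [read_manifest()].
#' @return A list with `sweep`, `selection`, `fit`, `counts_at_tau_star`,
#'   `output_dir`, `manifest_hash`, and the `log`.
#' @export
run_end_to_end <- function(manifest) {
  manifest <- read_manifest(manifest)
  out_dir <- manifest$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  log <- new_run_log(log_path)
  hash <- manifest_hash(manifest)
  version <- as.character(utils::packageVersion("blinkcount"))
  log_event(log, "run", "start", manifest_hash = hash, version = version,
            seed = manifest$seed)

  log_event(log, "load", "start", n_movies = length(manifest$movies))
  movies <- lapply(manifest$movies, function(m) {
    st <- if (!is.null(m$path))
      load_stack(m$path, pixel_size = m$pixel_size, exposure_s = m$exposure_s)
    else m$stack
    movie_record(m$label, m$concentration, st)
  })
  log_event(log, "load", "end")

  log_event(log, "sweep", "start",
            kernel = paste(manifest$filter$kernel, collapse = ","),
            boundary = manifest$filter$boundary,
            taus = paste(manifest$taus, collapse = ","))
  sweep <- sweep_thresholds(movies, manifest$taus, manifest$filter)
  log_event(log, "sweep", "end", n_cells = length(sweep$counts))

  log_event(log, "select", "start")
  selection <- withCallingHandlers(
    select_threshold(sweep),
    warning = function(w) {
      log_event(log, "select", "warning", message = conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  log_event(log, "select", "end", tau_star = selection$tau_star,
            monotone_found = selection$monotone_found)

  jstar <- match(selection$tau_star, sweep$taus)
  counts_star <- sweep$counts[, jstar]
  fit <- fit_log_linear(sweep$concentrations, counts_star)
  log_event(log, "calibrate", "end", slope = fit$slope,
            intercept = fit$intercept,
            r_squared = if (fit$r_squared_defined) fit$r_squared else NA)

  # ---- outputs (no timestamps: byte-identical reruns are a contract) ----
  sweep_df <- data.frame(
    label = rep(sweep$labels, times = length(sweep$taus)),
    concentration_pg_per_ml = rep(sweep$concentrations,
                                  times = length(sweep$taus)),
    tau = rep(sweep$taus, each = length(sweep$labels)),
    count = as.vector(sweep$counts)
  )
  utils::write.csv(sweep_df, file.path(out_dir, "sweep.csv"),
                   row.names = FALSE)

  fit_record <- list(
    software = "blinkcount", version = version, manifest_hash = hash,
    seed = manifest$seed,
    filter = list(kernel = manifest$filter$kernel,
                  boundary = manifest$filter$boundary),
    taus_screened = sweep$taus,
    tau_star = selection$tau_star,
    monotone_found = selection$monotone_found,
    counts_at_tau_star = as.list(stats::setNames(counts_star, sweep$labels)),
    calibration = list(
      slope = fit$slope, intercept = fit$intercept,
      r_squared = if (fit$r_squared_defined) fit$r_squared else NULL,
      r_squared_defined = fit$r_squared_defined,
      n_points = fit$n_points, x_definition = fit$x_definition),
    conventions = "frames 1-based; coordinates (y, x) px, origin top-left"
  )
  jsonlite::write_json(fit_record, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  for (i in seq_along(movies)) {
    filt <- median_filter_stack(resolve_stack(movies[[i]]$stack),
                                manifest$filter)
    det <- detect_stack(filt, detector_params(selection$tau_star))
    mask8 <- matrix(as.numeric(det$mask) * 255, nrow(det$mask), ncol(det$mask))
    save_stack(image_stack(mask8, dtype = "uint8"),
               file.path(out_dir, "masks",
                         paste0(gsub("[^A-Za-z0-9._-]", "_",
                                     movies[[i]]$label), "_mask.tif")))
  }

  summary_lines <- c(
    "blinkcount end-to-end run",
    sprintf("version: %s  manifest_hash: %s  seed: %s",
            version, hash, manifest$seed),
    sprintf("filter kernel (t,y,x): (%s), boundary %s",
            paste(manifest$filter$kernel, collapse = ","),
            manifest$filter$boundary),
    sprintf("thresholds screened: %s", paste(sweep$taus, collapse = ", ")),
    sprintf("selected tau* = %g (monotone concentration response: %s)",
            selection$tau_star, selection$monotone_found),
    sprintf("calibration: count = %.6g * log10(conc pg/mL) + %.6g ; R^2 %s",
            fit$slope, fit$intercept,
            if (fit$r_squared_defined) sprintf("= %.4f", fit$r_squared)
            else "undefined"),
    "counts at tau* (per movie):",
    sprintf("  %-20s conc %10.4g pg/mL  N = %d",
            sweep$labels, sweep$concentrations, as.integer(counts_star)),
    "conventions: frames 1-based; coordinates (y, x) px, origin top-left"
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  log_event(log, "run", "end", tau_star = selection$tau_star)

  list(sweep = sweep, selection = selection, fit = fit,
       counts_at_tau_star = counts_star, output_dir = out_dir,
       manifest_hash = hash, log = log)
}
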