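#' Write a current trace to CSV with a JSON epoch sidecar
#'
#' The trace goes to \code{<path>} as a two-column CSV (\code{time_s},
#' \code{current_pA}); epochs go to \code{<path>} with the extension replaced
#' by \code{.epochs.json} (fields \code{name}, \code{start_s}, \code{end_s},
#' \code{solution}, \code{conc_um}).
#'
#' @param trace a [current_trace()].
#' @param path CSV file path.
#' @return invisibly, c(csv = path, epochs = sidecar path).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  utils::write.csv(data.frame(time_s = trace$time,
                              current_pA = trace$current),
                   path, row.names = FALSE)
  side <- epoch_sidecar_path(path)
  jsonlite::write_json(trace$epochs, side, digits = NA, dataframe = "rows")
  invisible(c(csv = path, epochs = side))
}

#' Read a current trace written by [write_trace()]
#'
#' @param path CSV file path; the epoch sidecar is looked up next to it
#'   unless \code{epochs_path} is given.
#' @param epochs_path optional explicit sidecar path.
#' @return a [current_trace()].
#' @export
read_trace <- function(path, epochs_path = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  tab <- utils::read.csv(path)
  if (!all(c("time_s", "current_pA") %in% names(tab))) {
    stop("trace CSV must have columns time_s, current_pA")
  }
  side <- epochs_path %||% epoch_sidecar_path(path)
  if (!file.exists(side)) stop("epoch sidecar not found: ", side)
  epochs <- as.data.frame(jsonlite::read_json(side, simplifyVector = TRUE))
  if (is.null(epochs$conc_um)) epochs$conc_um <- NA_real_
  current_trace(tab$time_s, tab$current_pA, epochs)
}

epoch_sidecar_path <- function(path) {
  sub("\\.[^.]+$", "", path) |> paste0(".epochs.json")
}

#' Serialize a gating scheme to JSON
#'
#' Flat JSON with keys kd, kr, ko, kc, kb, blocker_conc, ku and a units
#' comment field. Read back with [read_gating_scheme()].
#'
#' @param scheme a [gating_scheme()].
#' @param path JSON file path.
#' @export
write_gating_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "gating_scheme"))
  jsonlite::write_json(
    list(units = "rates 1/s; kb 1/(uM s); blocker_conc uM",
         kd = scheme$kd, kr = scheme$kr, ko = scheme$ko, kc = scheme$kc,
         kb = scheme$kb, blocker_conc = scheme$blocker_conc,
         ku = scheme$ku),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gating_scheme
#' @export
read_gating_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gating_scheme(kd = x$kd, kr = x$kr, ko = x$ko, kc = x$kc, kb = x$kb,
                blocker_conc = x$blocker_conc, ku = x$ku %||% 0)
}

#' Write a state trajectory as tidy CSV
#'
#' Columns \code{time_s, D, C, O, B}, as produced by [simulate_scheme()].
#'
#' @param trajectory data.frame from [simulate_scheme()].
#' @param path CSV path.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}

#' Read a dose-response CSV
#'
#' Expected columns: \code{conc_um}, \code{response}, optional
#' \code{cell_id}.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_dose_response <- function(path) {
  if (!file.exists(path)) stop("dose-response file not found: ", path)
  tab <- utils::read.csv(path)
  if (!all(c("conc_um", "response") %in% names(tab))) {
    stop("dose-response CSV must have columns conc_um, response")
  }
  tab
}

#' Read a nuclear-area CSV
#'
#' Expected columns: \code{area_um2}, optional \code{nucleus_id},
#' \code{condition}, \code{infected_flag}.
#'
#' @param path CSV path.
#' @return data.frame (missing \code{condition} filled with "all").
#' @export
read_nuclei <- function(path) {
  if (!file.exists(path)) stop("nuclei file not found: ", path)
  tab <- utils::read.csv(path)
  if (!"area_um2" %in% names(tab)) {
    stop("nuclei CSV must have a column area_um2")
  }
  if (is.null(tab$condition)) tab$condition <- "all"
  tab
}

#' Write an analysis result as JSON
#'
#' Serializes the fields of a fit object (class attributes dropped) with a
#' package-version provenance stamp.
#'
#' @param result a fit object or plain list.
#' @param path JSON path.
#' @export
write_result_json <- function(result, path) {
  out <- unclass(result)
  out$decay <- NULL  # drop bulky per-sample payloads
  out$posterior <- NULL
  out$data <- NULL
  out$package_version <-
    as.character(utils::packageVersion("nmdarkinetics"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Read/write an intensity raster as TIFF
#'
#' Thin wrappers around the tiff package (listed in Suggests); intensities
#' are stored as 32-bit floats scaled to the original range.
#'
#' @param raster numeric matrix.
#' @param path TIFF path.
#' @export
write_raster_tiff <- function(raster, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the tiff package is required for TIFF I/O")
  }
  tiff::writeTIFF(raster / max(raster, 1), path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_raster_tiff
#' @export
read_raster_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the tiff package is required for TIFF I/O")
  }
  tiff::readTIFF(path)
}

#' Run a configured analysis pipeline
#'
#' Executes the requested stages against the inputs named in a JSON config:
#' \describe{
#'   \item{estimate_po}{\code{trace} (CSV path) -> Po estimate.}
#'   \item{fit_exponential}{\code{trace}, \code{window} -> exponential fit.}
#'   \item{fit_hill / fit_inhibition}{\code{dose} (CSV path) -> Hill fit.}
#'   \item{classify_nuclei}{\code{nuclei} (CSV path) -> pooled mixture fit
#'     and per-condition pyknotic fractions.}
#'   \item{classify_spines}{\code{spines} (CSV path) -> spine classes and
#'     the percentage table.}
#' }
#' Results are returned as a named list and, when \code{out_dir} is set in
#' the config, written as JSON files stamped with the config hash and
#' package version. An empty stage list is a no-op with a warning.
#'
#' @param config path to a JSON config, or an equivalent named list with
#'   elements \code{stages} (character vector), \code{inputs} (named list of
#'   file paths), optional \code{params} and \code{out_dir} and \code{seed}.
#' @return named list of stage results (invisible when written to disk).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfg_text <- readLines(config, warn = FALSE)
    config <- jsonlite::fromJSON(paste(cfg_text, collapse = "\n"),
                                 simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config error: config must be a list or path")
  stages <- config$stages
  if (is.null(stages) || length(stages) == 0) {
    warning("empty stage list: nothing to do")
    return(invisible(list()))
  }
  known <- c("estimate_po", "fit_exponential", "fit_hill", "fit_inhibition",
             "classify_nuclei", "classify_spines")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop("config error at stages: unknown stage(s) ",
         paste(bad, collapse = ", "))
  }
  inputs <- config$inputs %||% list()
  params <- config$params %||% list()
  seed <- config$seed %||% 1
  need <- function(field) {
    p <- inputs[[field]]
    if (is.null(p)) stop("config error at inputs$", field, ": missing")
    p
  }
  results <- list()
  for (st in stages) {
    results[[st]] <- switch(st,
      estimate_po = {
        tr <- read_trace(need("trace"))
        do.call(estimate_po, c(list(trace = tr),
                               params$estimate_po %||% list()))
      },
      fit_exponential = {
        tr <- read_trace(need("trace"))
        win <- params$fit_exponential$window %||% "agonist"
        fit_exponential(tr, window = win)
      },
      fit_hill = {
        tab <- read_dose_response(need("dose"))
        fit_dose_response_by_cell(tab, "activation")
      },
      fit_inhibition = {
        tab <- read_dose_response(need("dose"))
        fit_dose_response_by_cell(tab, "inhibition")
      },
      classify_nuclei = {
        tab <- read_nuclei(need("nuclei"))
        pyknosis_by_condition(tab, seed = seed)
      },
      classify_spines = {
        tab <- utils::read.csv(need("spines"))
        cl <- classify_spines(tab)
        list(classified = cl, table = spine_type_table(cl))
      })
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- list(config_hash = config_hash(config),
                  package_version =
                    as.character(utils::packageVersion("nmdarkinetics")))
    for (st in names(results)) {
      res <- results[[st]]
      payload <- if (is.list(res)) res else list(value = res)
      payload$provenance <- stamp
      write_result_json(payload,
                        file.path(config$out_dir, paste0(st, ".json")))
    }
  }
  invisible(results)
}

# Stable hash of the config for output provenance (no extra dependencies:
# a simple polynomial rolling hash over the serialized config).
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 1e9
  sprintf("%09.0f", h)
}
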