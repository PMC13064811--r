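#' Surface-to-total fluorescence ratio
#'
#' Ratio of mean surface-channel to mean total-channel intensity within the
#' cell mask. The mean intensity of the non-cell region of each channel is
#' subtracted first (uniform-background correction), making the ratio
#' invariant to a common multiplicative gain and to an additive background.
#'
#' @param surface,total intensity matrices (congruent).
#' @param cell_mask logical matrix marking the cell.
#' @param background_subtract subtract the non-cell mean (default TRUE).
#' @return ratio (dimensionless).
#' @export
surface_total_ratio <- function(surface, total, cell_mask,
                                background_subtract = TRUE) {
  check_rasters(surface, total, cell_mask)
  if (!any(cell_mask)) stop("cell mask is empty")
  bg_s <- bg_t <- 0
  if (background_subtract && any(!cell_mask)) {
    bg_s <- mean(surface[!cell_mask])
    bg_t <- mean(total[!cell_mask])
  }
  denom <- mean(total[cell_mask]) - bg_t
  if (abs(denom) < 1e-12) stop("undefined ratio: no total signal in cell")
  (mean(surface[cell_mask]) - bg_s) / denom
}

#' Marker colocalization ratio
#'
#' Mean reporter intensity inside the marker-defined region divided by the
#' mean intensity in the rest of the cell (cell minus marker region), after
#' uniform-background subtraction. This is the Golgi-retention style metric:
#' values well above 1 indicate enrichment in the marker compartment.
#'
#' @param signal reporter-channel intensity matrix.
#' @param marker_mask logical matrix of the marker-positive region.
#' @param cell_mask logical matrix of the cell.
#' @param background_subtract subtract the non-cell mean (default TRUE).
#' @return ratio (dimensionless).
#' @export
colocalization_ratio <- function(signal, marker_mask, cell_mask,
                                 background_subtract = TRUE) {
  check_rasters(signal, marker_mask, cell_mask)
  inside <- marker_mask & cell_mask
  outside <- cell_mask & !marker_mask
  if (!any(inside) || !any(outside)) {
    stop("marker region and its complement within the cell must both be",
         " non-empty")
  }
  bg <- if (background_subtract && any(!cell_mask))
    mean(signal[!cell_mask]) else 0
  denom <- mean(signal[outside]) - bg
  if (abs(denom) < 1e-12) {
    stop("undefined ratio: no signal outside the marker region")
  }
  (mean(signal[inside]) - bg) / denom
}

#' Build a marker mask from a marker channel
#'
#' Thresholds the marker channel at mean + \code{k} sd of the in-cell marker
#' intensity (the threshold is a declared parameter, not an inference of any
#' particular acquisition pipeline).
#'
#' @param marker marker-channel intensity matrix.
#' @param cell_mask logical cell mask.
#' @param k threshold stringency in sd units (default 2).
#' @return logical matrix.
#' @export
marker_mask_from_channel <- function(marker, cell_mask, k = 2) {
  check_rasters(marker, cell_mask)
  if (!any(cell_mask)) stop("cell mask is empty")
  v <- marker[cell_mask]
  thr <- mean(v) + k * stats::sd(v)
  marker > thr & cell_mask
}

check_rasters <- function(...) {
  ms <- list(...)
  dims <- lapply(ms, dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      !all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("rasters and masks must be congruent matrices")
  }
  invisible(TRUE)
}

#' Classify a dendritic spine by head/neck geometry
#'
#' Morphological rules: mushroom = head diameter >= 0.35 um with a distinct
#' neck and head/neck ratio >= 1.1; stubby = head >= 0.35 um, no distinct
#' neck, directly attached to the dendrite; thin = a visible but smaller
#' head (< 0.35 um), or a large head whose head/neck ratio falls below 1.1
#' (flagged for audit); filopodia = no visible head.
#'
#' @param head_um head diameter, um, or NA when no visible head.
#' @param neck_um neck diameter, um, or NA when no distinct neck.
#' @param has_visible_head logical.
#' @param directly_attached logical; TRUE when the protrusion sits on the
#'   dendrite without a distinct neck.
#' @param min_head_um minimum mushroom/stubby head diameter (default 0.35).
#' @param min_head_neck_ratio minimum mushroom head/neck ratio (default 1.1).
#' @return list with \code{class} (one of "mushroom", "stubby", "thin",
#'   "filopodia") and \code{flag} (\code{"low_head_neck_ratio"} for the
#'   audited boundary case, else \code{NA}).
#' @examples
#' classify_spine(0.40, 0.30, TRUE, FALSE)$class  # mushroom
#' classify_spine(NA, NA, FALSE, TRUE)$class      # filopodia
#' @export
classify_spine <- function(head_um, neck_um, has_visible_head,
                           directly_attached, min_head_um = 0.35,
                           min_head_neck_ratio = 1.1) {
  if (!has_visible_head) {
    if (!is.na(head_um)) {
      stop("inconsistent spine measure: head diameter given without a",
           " visible head")
    }
    return(list(class = "filopodia", flag = NA_character_))
  }
  if (is.na(head_um) || head_um <= 0) {
    stop("visible head requires a positive head diameter")
  }
  if (!is.na(neck_um) && neck_um <= 0) stop("neck diameter must be positive")
  if (head_um >= min_head_um) {
    if (!is.na(neck_um)) {
      if (head_um / neck_um >= min_head_neck_ratio) {
        return(list(class = "mushroom", flag = NA_character_))
      }
      return(list(class = "thin", flag = "low_head_neck_ratio"))
    }
    if (directly_attached) {
      return(list(class = "stubby", flag = NA_character_))
    }
    # no measurable neck yet not directly attached: closest category is thin
    return(list(class = "thin", flag = "no_neck_not_attached"))
  }
  list(class = "thin", flag = NA_character_)
}

#' Classify a table of spine measurements
#'
#' @param spines data.frame with columns \code{head_um}, \code{neck_um},
#'   \code{has_head} (logical), \code{attached} (logical) and optionally
#'   \code{spine_id}, \code{condition}.
#' @param ... thresholds passed to [classify_spine()].
#' @return the input with added \code{class} and \code{flag} columns.
#' @export
classify_spines <- function(spines, ...) {
  req <- c("head_um", "neck_um", "has_head", "attached")
  if (!all(req %in% names(spines))) {
    stop("spines must have columns ", paste(req, collapse = ", "))
  }
  res <- lapply(seq_len(nrow(spines)), function(i) {
    classify_spine(spines$head_um[i], spines$neck_um[i],
                   spines$has_head[i], spines$attached[i], ...)
  })
  spines$class <- vapply(res, `[[`, character(1), "class")
  spines$flag <- vapply(res, `[[`, character(1), "flag")
  spines
}

#' Spine-type percentage table
#'
#' Percentages of the four morphological classes, per condition when a
#' \code{condition} column is present; each row sums to 100.
#'
#' @param classified output of [classify_spines()].
#' @return data.frame with columns \code{condition}, \code{mushroom},
#'   \code{stubby}, \code{thin}, \code{filopodia}, \code{n} (percent
#'   columns).
#' @export
spine_type_table <- function(classified) {
  if (!"class" %in% names(classified)) {
    stop("input must be classified with classify_spines()")
  }
  cond <- classified$condition %||% rep("all", nrow(classified))
  types <- c("mushroom", "stubby", "thin", "filopodia")
  rows <- lapply(split(classified$class, cond), function(cl) {
    pct <- 100 * vapply(types, function(ty) mean(cl == ty), numeric(1))
    c(pct, n = length(cl))
  })
  out <- data.frame(condition = names(rows),
                    do.call(rbind, rows), row.names = NULL)
  names(out) <- c("condition", types, "n")
  out
}
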