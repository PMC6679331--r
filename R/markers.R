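#' Labelled time intervals (markers)
#'
#' Markers are closed-open intervals `[start_s, end_s)` in seconds with a
#' label drawn from the session vocabulary: `artifact` regions to excise,
#' and the protocol segments `rest`, `motion_drive`, `no_motion_drive`,
#' `test_drive`. Overlapping or touching intervals with the same label
#' are merged on construction, so same-label intervals are always
#' disjoint and sorted.
#'
#' @param start_s,end_s Numeric vectors of interval bounds in seconds,
#'   `start_s < end_s`, all non-negative.
#' @param label Character vector of labels (recycled if length 1).
#' @return A tibble with columns `start_s`, `end_s`, `label`, normalised.
#' @export
#' @examples
#' markers(c(10, 15), c(20, 25), "artifact") # merged to one interval
markers <- function(start_s = numeric(), end_s = numeric(),
                    label = character()) {
  if (length(label) == 1 && length(start_s) > 1) {
    label <- rep(label, length(start_s))
  }
  df <- tibble::tibble(start_s = as.numeric(start_s),
                       end_s = as.numeric(end_s),
                       label = as.character(label))
  normalize_markers(df)
}

marker_labels <- c("artifact", "rest", "motion_drive", "no_motion_drive",
                   "test_drive")

#' Normalise a marker table
#'
#' Validates bounds and labels, then merges overlapping or touching
#' intervals that share a label. Idempotent.
#'
#' @param df Data frame with columns `start_s`, `end_s`, `label`.
#' @return A normalised marker tibble, sorted by label then start.
#' @export
normalize_markers <- function(df) {
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(df))) {
    stop("marker format error: need columns start_s, end_s, label",
         call. = FALSE)
  }
  df <- tibble::as_tibble(df)[need]
  if (nrow(df) == 0) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric(),
                          label = character()))
  }
  bad <- setdiff(unique(df$label), marker_labels)
  if (length(bad) > 0) {
    stop("marker format error: unknown label(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(df$start_s < 0)) {
    stop("marker format error: negative start time", call. = FALSE)
  }
  if (any(df$end_s <= df$start_s)) {
    stop("marker format error: end_s must exceed start_s", call. = FALSE)
  }
  df |>
    dplyr::group_by(.data$label) |>
    dplyr::group_modify(~ merge_intervals(.x)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$label, .data$start_s) |>
    dplyr::select("start_s", "end_s", "label")
}

# union of closed-open intervals within one label
merge_intervals <- function(df) {
  df <- df[order(df$start_s), ]
  out_s <- df$start_s[1]
  out_e <- df$end_s[1]
  for (i in seq_len(nrow(df))[-1]) {
    k <- length(out_s)
    if (df$start_s[i] <= out_e[k]) {
      out_e[k] <- max(out_e[k], df$end_s[i])
    } else {
      out_s <- c(out_s, df$start_s[i])
      out_e <- c(out_e, df$end_s[i])
    }
  }
  tibble::tibble(start_s = out_s, end_s = out_e)
}

#' Read markers from CSV
#'
#' @param path CSV with columns `start_s`, `end_s`, `label`. An empty file
#'   with only the header yields an empty marker set.
#' @return A normalised marker tibble.
#' @export
read_markers <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          start_s = readr::col_double(),
                          end_s = readr::col_double(),
                          label = readr::col_character()
                        ))
  normalize_markers(df)
}

#' Write markers to CSV
#'
#' @param df A marker tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(df, path) {
  readr::write_csv(normalize_markers(df), path, progress = FALSE)
  invisible(path)
}
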