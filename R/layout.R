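#' Default electrode-array layout
#'
#' The array wraps the forearm with two 4-row panels: an inner (flexor-side)
#' panel and an outer (extensor-side) panel.  With the default 96 electrodes
#' each panel is 4 rows x 12 columns; the flexor panel carries labels
#' A1--A32 plus C1--C16 and the extensor panel B1--B32 plus C17--C32.
#' Electrodes are wired in groups of four, so labels run down each column in
#' a zigzag (down the odd columns, up the even ones).
#'
#' @param n_channels Total electrode count; must be a positive multiple of 8
#'   (4 rows per panel, two panels).  Default 96.
#' @return A data.frame of class `ff_layout` with columns `label`, `group`
#'   (A/B/C), `side` (`"flexor"`/`"extensor"`), `grid_row` (1..4) and
#'   `grid_col` (panel column, 1-based).
#' @examples
#' lay <- default_layout()
#' table(lay$side)
#' @export
default_layout <- function(n_channels = 96L) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 8L || n_channels %% 8L != 0L)
    stop("n_channels must be a positive multiple of 8, got ", n_channels)
  per_side <- n_channels %/% 2L
  panel_cols <- per_side %/% 4L

  side_labels <- function(prefix, c_offset) {
    n_main <- min(32L, per_side)
    lab <- paste0(prefix, seq_len(n_main))
    grp <- rep(prefix, n_main)
    if (per_side > 32L) {
      lab <- c(lab, paste0("C", c_offset + seq_len(per_side - 32L)))
      grp <- c(grp, rep("C", per_side - 32L))
    }
    list(label = lab, group = grp)
  }

  panel_coords <- function() {
    i <- seq_len(per_side) - 1L
    col <- i %/% 4L + 1L
    within <- i %% 4L
    row <- ifelse(col %% 2L == 1L, within + 1L, 4L - within)
    data.frame(grid_row = row, grid_col = col)
  }

  fl <- side_labels("A", 0L)
  ex <- side_labels("B", if (per_side > 32L) per_side - 32L else 0L)
  out <- rbind(
    cbind(data.frame(label = fl$label, group = fl$group,
                     side = "flexor", stringsAsFactors = FALSE),
          panel_coords()),
    cbind(data.frame(label = ex$label, group = ex$group,
                     side = "extensor", stringsAsFactors = FALSE),
          panel_coords())
  )
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$label))
  class(out) <- c("ff_layout", "data.frame")
  out
}

#' Default anatomical channel mask
#'
#' Assigns each finger a contiguous block of electrodes on each panel, the
#' region where its flexor (inner panel) or extensor (outer panel) muscle is
#' expected.  Blocks are ordered Thumb to Pinky along the proximal--distal
#' panel axis and span all 4 rows by up to 2 columns.
#'
#' @param layout An `ff_layout`, e.g. [default_layout()].
#' @return A data.frame of class `ff_channel_mask` with columns `finger`,
#'   `direction` (`"flexion"`/`"extension"`) and `label`.
#' @export
default_channel_mask <- function(layout = default_layout()) {
  stopifnot(inherits(layout, "ff_layout"))
  panel_cols <- max(layout$grid_col)
  if (panel_cols < 5L)
    stop("layout needs at least 5 panel columns for a per-finger mask")
  cols_per <- max(1L, min(2L, panel_cols %/% 5L))
  rows <- list()
  for (f in seq_along(.FINGERS)) {
    c0 <- floor((f - 1L) * panel_cols / 5) + 1L
    cols <- c0:(c0 + cols_per - 1L)
    for (dir in c("flexion", "extension")) {
      side <- if (dir == "flexion") "flexor" else "extensor"
      lab <- layout$label[layout$side == side & layout$grid_col %in% cols]
      rows[[length(rows) + 1L]] <- data.frame(
        finger = .FINGERS[f], direction = dir, label = lab,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ff_channel_mask", "data.frame")
  validate_channel_mask(out, layout)
  out
}

#' @keywords internal
validate_channel_mask <- function(mask, layout) {
  if (!all(mask$label %in% layout$label))
    stop("channel mask refers to labels missing from the layout")
  side_of <- stats::setNames(layout$side, layout$label)
  bad_flex <- mask$direction == "flexion" & side_of[mask$label] != "flexor"
  bad_ext <- mask$direction == "extension" & side_of[mask$label] != "extensor"
  if (any(bad_flex) || any(bad_ext))
    stop("mask assigns channels to the wrong panel side")
  invisible(mask)
}

#' Look up the masked channels for one finger and direction
#'
#' @param mask An `ff_channel_mask`.
#' @param finger Finger name (see [finger_names()]).
#' @param direction `"flexion"` or `"extension"`.
#' @return Character vector of channel labels; errors if the set is empty.
#' @export
mask_labels <- function(mask, finger, direction) {
  stopifnot(inherits(mask, "ff_channel_mask"))
  direction <- match.arg(direction, c("flexion", "extension"))
  lab <- mask$label[mask$finger == finger & mask$direction == direction]
  if (length(lab) == 0L)
    stop("empty channel mask for (", finger, ", ", direction, ")")
  lab
}
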