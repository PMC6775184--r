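## Correlation-based selection of per-finger flexor/extensor signals.
##
## Targets are direction-specific half-wave rectified angles: the flexion
## target is max(theta, 0), the extension target max(-theta, 0), so a
## flexor envelope correlates with the flexion target and an extensor
## envelope with the extension target.  Both routes (raw channels under the
## anatomical mask, and independent components) use the same envelopes and
## the same targets.

direction_target <- function(traj, finger, direction) {
  th <- traj$angles[finger, ]
  if (direction == "flexion") pmax(th, 0) else pmax(-th, 0)
}

selection_result <- function(candidates, chosen, finger, direction, kind) {
  structure(list(candidates = candidates, chosen = chosen,
                 finger = finger, direction = direction, kind = kind),
            class = "ff_selection")
}

#' @export
print.ff_selection <- function(x, ...) {
  cat(sprintf("<ff_selection> %s/%s [%s]: chose %s (cc=%.3f) of %d candidates\n",
              x$finger, x$direction, x$kind, x$chosen,
              x$candidates$cc[match(x$chosen, x$candidates$id)],
              nrow(x$candidates)))
  invisible(x)
}

#' Rank independent components by correlation with a finger's motion
#'
#' Computes the Pearson correlation between every component's envelope and
#' the direction-specific rectified ground-truth angle, returns the top 16
#' by absolute correlation together with their topology artifact flags, and
#' picks the best unflagged candidate (ties broken by lower component
#' index).  Flagged components (motion-noise spread, detached-sensor
#' bipolar patterns) are skipped exactly as a human inspecting topology
#' plots would reject them.
#'
#' @param decomp An `ff_ica` fit whose `sources` are at the trajectory rate.
#' @param traj Ground-truth [finger_trajectory()] aligned with the sources.
#' @param finger,direction Which target to match.
#' @param layout Array layout for the topology heuristics.
#' @param n_top Number of ranked candidates to return (default 16).
#' @param cutoff Envelope low-pass cut-off (Hz).
#' @return An `ff_selection`; `candidates` has columns `id`, `component`,
#'   `cc`, `spread`, `motion_noise`, `detach`.
#' @export
rank_components_by_cc <- function(decomp, traj, finger, direction, layout,
                                  n_top = 16L, cutoff = 3) {
  stopifnot(inherits(decomp, "ff_ica"), inherits(traj, "ff_trajectory"))
  direction <- match.arg(direction, c("flexion", "extension"))
  if (decomp$retained_rank < 1L) stop("empty decomposition")
  if (!is.null(decomp$fs) && abs(decomp$fs - traj$fs) > 1e-9)
    stop("decomposition and trajectory sampling rates differ")
  env <- emg_envelope(decomp$sources, fs = traj$fs, cutoff = cutoff,
                      source_kind = "independent_component")
  rank_envelopes_by_cc(env, traj, finger, direction, decomp, layout, n_top)
}

rank_envelopes_by_cc <- function(env, traj, finger, direction, decomp,
                                 layout, n_top) {
  target <- direction_target(traj, finger, direction)
  if (ncol(env$env) != length(target))
    stop("envelope and trajectory lengths differ")
  cc <- apply(env$env, 1L, function(e) correlation_coefficient(e, target))
  comp <- seq_len(nrow(env$env))
  ord <- order(-abs(cc), comp, na.last = TRUE)
  keep <- utils::head(ord, n_top)
  topo <- lapply(keep, function(k) ic_topology(decomp, layout, k))
  cand <- data.frame(
    id = paste0("IC", keep), component = keep, cc = cc[keep],
    spread = vapply(topo, `[[`, numeric(1), "spread"),
    motion_noise = vapply(topo, `[[`, logical(1), "motion_noise"),
    detach = vapply(topo, `[[`, logical(1), "detach"),
    stringsAsFactors = FALSE)
  ok <- !cand$motion_noise & !cand$detach & !is.na(cand$cc)
  chosen <- if (any(ok)) cand$id[which(ok)[1L]] else cand$id[1L]
  selection_result(cand, chosen, finger, direction, "independent_component")
}

#' Select the best raw channel within the anatomical mask
#'
#' Restricts the candidates to the electrodes where the finger's muscle is
#' anatomically expected, then picks the channel whose envelope has the
#' highest absolute correlation with the direction-specific rectified
#' ground-truth angle.  Ties are broken by lower grid row, then lower grid
#' column.
#'
#' @param envelopes An `ff_envelopes` over the array channels (ids must be
#'   channel labels).
#' @param traj Ground-truth [finger_trajectory()] at the envelope rate.
#' @param mask An `ff_channel_mask`.
#' @param finger,direction Which target to match.
#' @param layout Array layout (for the tie-break coordinates).
#' @return An `ff_selection`; `candidates` has columns `id`, `cc`,
#'   `grid_row`, `grid_col`.
#' @export
select_channels <- function(envelopes, traj, mask, finger, direction,
                            layout = default_layout()) {
  stopifnot(inherits(envelopes, "ff_envelopes"),
            inherits(traj, "ff_trajectory"))
  direction <- match.arg(direction, c("flexion", "extension"))
  labels <- mask_labels(mask, finger, direction)
  miss <- setdiff(labels, envelopes$ids)
  if (length(miss)) stop("mask channels missing from envelopes: ",
                         paste(miss, collapse = ", "))
  target <- direction_target(traj, finger, direction)
  if (ncol(envelopes$env) != length(target))
    stop("envelope and trajectory lengths differ")
  rows <- match(labels, envelopes$ids)
  cc <- apply(envelopes$env[rows, , drop = FALSE], 1L,
              function(e) correlation_coefficient(e, target))
  li <- match(labels, layout$label)
  cand <- data.frame(id = labels, cc = cc,
                     grid_row = layout$grid_row[li],
                     grid_col = layout$grid_col[li],
                     stringsAsFactors = FALSE)
  ord <- order(-abs(cand$cc), cand$grid_row, cand$grid_col, na.last = TRUE)
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  selection_result(cand, cand$id[1L], finger, direction, "raw_channel")
}
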