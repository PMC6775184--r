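#' Independent component analysis of a multichannel recording
#'
#' Whitens the (centered) channel data by SVD, keeping the leading subspace,
#' then runs symmetric fixed-point ICA with the log-cosh (super-Gaussian)
#' contrast.  EMG interference sources -- muscles, line pickup, motion
#' artifacts -- are super-Gaussian and statistically independent, which is
#' exactly the regime this contrast separates.  The run is deterministic for
#' a given `seed`; non-convergence (e.g. near-Gaussian sources, for which
#' ICA is not identifiable) is reported via the `converged` flag rather than
#' an error, with the partial result returned.
#'
#' @param x An [emg_recording()] (band-passed and resampled) or a bare
#'   channels-x-samples matrix.
#' @param n_components `"auto"` (keep the subspace explaining
#'   `1 - 1e-6` of the variance) or an integer count.
#' @param seed Integer seed for the orthonormal initialisation.
#' @param fs Sampling rate; taken from the recording when one is given.
#' @param maxit,tol Fixed-point iteration limit and convergence tolerance.
#' @return An `ff_ica` object: `unmixing` (components x channels),
#'   `mixing` (channels x components, the pseudo-inverse), `sources`
#'   (components x samples), `retained_rank`, `center`, `fs`, `seed`,
#'   `converged`, `iterations`.  `unmixing %*% mixing` is the identity on
#'   the retained subspace and `sources = unmixing %*% (x - center)`.
#' @export
fit_ica <- function(x, n_components = "auto", seed = 1L, fs = NULL,
                    maxit = 200L, tol = 1e-6) {
  if (inherits(x, "ff_recording")) { fs <- x$fs; x <- x$data }
  x <- as.matrix(x)
  nch <- nrow(x); n <- ncol(x)
  if (n <= nch) stop("need more samples than channels")
  ctr <- rowMeans(x)
  xc <- x - ctr

  sv <- svd(xc / sqrt(n - 1), nu = nch, nv = 0)
  ev <- sv$d^2
  if (sum(ev) <= 0) stop("zero-rank input")
  cum <- cumsum(ev) / sum(ev)
  r_auto <- which(cum >= 1 - 1e-6)[1L]
  r <- if (identical(n_components, "auto")) r_auto
       else min(as.integer(n_components), sum(ev > max(ev) * 1e-12))
  if (r < 1L) stop("zero-rank input")

  ## whitening: z = K xc has unit covariance
  K <- diag(1 / sv$d[seq_len(r)], r) %*% t(sv$u[, seq_len(r), drop = FALSE])
  z <- K %*% xc

  W <- with_seed(seed, {
    m0 <- matrix(stats::rnorm(r * r), r, r)
    qr.Q(qr(m0))
  })
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), r) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    wz <- W %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    W_new <- (g %*% t(z)) / n - diag(rowMeans(gp), r) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }

  unmixing <- W %*% K
  ## pseudo-inverse in closed form: K^+ = U_r D_r, W orthonormal
  mixing <- sv$u[, seq_len(r), drop = FALSE] %*%
    diag(sv$d[seq_len(r)], r) %*% t(W)
  sources <- W %*% z
  rownames(sources) <- paste0("IC", seq_len(r))
  structure(list(unmixing = unmixing, mixing = mixing, sources = sources,
                 retained_rank = r, center = ctr, fs = fs, seed = seed,
                 converged = converged, iterations = it),
            class = "ff_ica")
}

#' Project new data onto fitted independent components
#'
#' @param decomp An `ff_ica` fit.
#' @param x Recording or channels-x-samples matrix with the same channels.
#' @return Components x samples source matrix.
#' @export
ica_sources <- function(decomp, x) {
  stopifnot(inherits(decomp, "ff_ica"))
  if (inherits(x, "ff_recording")) x <- x$data
  if (nrow(x) != length(decomp$center)) stop("channel count mismatch")
  s <- decomp$unmixing %*% (x - decomp$center)
  rownames(s) <- paste0("IC", seq_len(nrow(s)))
  s
}

#' Amari separation index
#'
#' Permutation- and scale-invariant distance between an estimated unmixing
#' matrix and the true mixing matrix.  For `P = W_est %*% A_true` (N x N):
#' `(1 / (2N(N-1))) * (sum_i (sum_j |P_ij| / max_j |P_ij| - 1) +
#'                     sum_j (sum_i |P_ij| / max_i |P_ij| - 1))`.
#' Zero if and only if `P` is a scaled permutation, i.e. perfect separation.
#'
#' @param estimated_unmixing Components x channels matrix.
#' @param true_mixing Channels x sources matrix; the product must be square.
#' @return Non-negative scalar.
#' @export
amari_index <- function(estimated_unmixing, true_mixing) {
  P <- abs(estimated_unmixing %*% true_mixing)
  N <- nrow(P)
  if (N != ncol(P)) stop("estimated_unmixing %*% true_mixing must be square")
  row_term <- sum(rowSums(P / apply(P, 1L, max)) - 1)
  col_term <- sum(colSums(sweep(P, 2L, apply(P, 2L, max), "/")) - 1)
  (row_term + col_term) / (2 * N * (N - 1))
}

#' Electrode-grid topology of one independent component
#'
#' Places the component's mixing weights at the electrode grid coordinates
#' and scores two artifact signatures used to vet components: a
#' *motion-noise* pattern (weight spread over a large area of the array)
#' and a *detached-sensor* pattern (one dominant electrode with an
#' opposite-sign neighbour of comparable weight).
#'
#' @param decomp An `ff_ica` fit on the array channels.
#' @param layout The [default_layout()]-style `ff_layout` describing the
#'   channel order of the decomposition.
#' @param component Component index (1-based).
#' @return An `ff_topology` list: `map` (data.frame label/side/row/col/
#'   weight), `spread` (fraction of channels with `|w| >= 0.5 max|w|`),
#'   `bipolar` (logical), `motion_noise` and `detach` flags.
#' @export
ic_topology <- function(decomp, layout, component) {
  stopifnot(inherits(decomp, "ff_ica"), inherits(layout, "ff_layout"))
  if (nrow(layout) != nrow(decomp$mixing))
    stop("layout and decomposition channel counts differ")
  if (component < 1L || component > decomp$retained_rank)
    stop("component index out of range")
  w <- decomp$mixing[, component]
  map <- data.frame(label = layout$label, side = layout$side,
                    grid_row = layout$grid_row, grid_col = layout$grid_col,
                    weight = w, stringsAsFactors = FALSE)
  wmax <- max(abs(w))
  big <- abs(w) >= 0.5 * wmax
  spread <- mean(big)
  dom <- which.max(abs(w))
  neigh <- layout$side == layout$side[dom] &
    abs(layout$grid_row - layout$grid_row[dom]) <= 1L &
    abs(layout$grid_col - layout$grid_col[dom]) <= 1L &
    seq_len(nrow(layout)) != dom
  bipolar <- any(neigh & big & sign(w) == -sign(w[dom]))
  structure(list(map = map, component = component, spread = spread,
                 bipolar = bipolar,
                 motion_noise = spread > 0.5, detach = bipolar),
            class = "ff_topology")
}

#' @export
print.ff_topology <- function(x, ...) {
  cat(sprintf("<ff_topology> IC%d spread=%.3f%s%s\n", x$component, x$spread,
              if (x$motion_noise) " [motion-noise]" else "",
              if (x$detach) " [detach]" else ""))
  invisible(x)
}

#' Plot an IC topology as a two-panel electrode map
#'
#' @param x An `ff_topology` from [ic_topology()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ff_topology <- function(x, ...) {
  m <- x$map
  wmax <- max(abs(m$weight))
  colf <- function(w) grDevices::rgb(pmax(w, 0) / wmax, 0, pmax(-w, 0) / wmax)
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in c("flexor", "extensor")) {
    ms <- m[m$side == s, ]
    graphics::plot(ms$grid_col, ms$grid_row, pch = 21,
                   bg = colf(ms$weight), cex = 2.2,
                   xlab = "", ylab = s, yaxt = "n",
                   main = if (s == "flexor")
                     sprintf("IC%d (spread %.2f)", x$component, x$spread)
                   else "", ...)
  }
  invisible(x)
}
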