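#' Per-pixel neuron responses for a channel image
#'
#' For every grid pixel the `side` x `side` patch centred there is extracted
#' (reflect-padded at the borders), whitened with the network's stored
#' transform and encoded into spike counts. `stride = 1` assigns a response
#' vector to every pixel; a larger stride computes responses on a coarser
#' grid for speed (bilinear upsampling of derived maps restores full
#' resolution).
#'
#' @param ch A channel image (numeric matrix), normalised to \[0, 1\].
#' @param net A fitted [v1net()].
#' @param stride Grid stride in pixels (default 1).
#' @param channel_tag Optional provenance label.
#' @return An object of class `"v1_response_map"`: list with `counts`
#'   (n_positions x K integer matrix), grid coordinates `gy`, `gx`, the
#'   image `height`/`width`, `stride` and `channel_tag`.
#' @export
compute_response_map <- function(ch, net, stride = 1L, channel_tag = "") {
  stopifnot(inherits(net, "v1net"), is.matrix(ch))
  cfg <- net$config
  g <- extract_patches_grid(ch, cfg$side, as.integer(stride))
  xw <- apply_whitener(g$x, net$whitener)
  counts <- encode_patches(xw, net$Q, net$W, net$theta, cfg$n_steps, cfg$eta)
  structure(list(counts = counts, gy = g$gy, gx = g$gx,
                 height = g$height, width = g$width,
                 stride = g$stride, K = cfg$K, channel_tag = channel_tag),
            class = "v1_response_map")
}

#' @export
print.v1_response_map <- function(x, ...) {
  cat(sprintf("v1 response map: %d x %d image, stride %d (%d positions), K = %d neurons%s\n",
              x$height, x$width, x$stride, nrow(x$counts), x$K,
              if (nzchar(x$channel_tag)) paste0(", channel ", x$channel_tag) else ""))
  cat(sprintf("  mean spike count %.3f, zero fraction %.3f\n",
              mean(x$counts), mean(x$counts == 0)))
  invisible(x)
}

#' Reconstruct patches or an image from spike counts
#'
#' A patch is reconstructed as the gain-scaled sum of receptive fields
#' weighted by spike counts, `gain * sum_i n_i Q_i`, then de-whitened back
#' to pixel space. For a response map, the reconstructed patches are
#' overlap-averaged into an image.
#'
#' @param responses Either an n x K spike-count matrix (patch
#'   reconstruction) or a `"v1_response_map"` (image reconstruction).
#' @param net The fitted [v1net()] that produced the responses.
#' @return A patch matrix (n x side^2, pixel space) or a reconstructed image
#'   matrix.
#' @export
reconstruct <- function(responses, net) {
  stopifnot(inherits(net, "v1net"))
  cfg <- net$config
  if (inherits(responses, "v1_response_map")) {
    rm <- responses
    patches <- unapply_whitener(net$gain * (rm$counts %*% net$Q),
                                net$whitener)
    return(.overlap_average(patches, rm, cfg$side))
  }
  if (is.null(dim(responses))) responses <- matrix(responses, nrow = 1)
  if (ncol(responses) != cfg$K)
    stop("response dimension does not match the network's K")
  unapply_whitener(net$gain * (responses %*% net$Q), net$whitener)
}

.overlap_average <- function(patches, rm, side) {
  off <- (side - 1L) %/% 2L
  acc <- matrix(0, rm$height, rm$width)
  wt <- matrix(0, rm$height, rm$width)
  ny <- length(rm$gy); nx <- length(rm$gx)
  k <- 0L
  for (jx in seq_len(nx)) {
    for (jy in seq_len(ny)) {
      k <- k + 1L
      rows <- rm$gy[jy] - off + 0:(side - 1L)
      cols <- rm$gx[jx] - off + 0:(side - 1L)
      ok_r <- rows >= 1L & rows <= rm$height
      ok_c <- cols >= 1L & cols <= rm$width
      pm <- matrix(patches[k, ], side, side)
      acc[rows[ok_r], cols[ok_c]] <- acc[rows[ok_r], cols[ok_c]] +
        pm[ok_r, ok_c, drop = FALSE]
      wt[rows[ok_r], cols[ok_c]] <- wt[rows[ok_r], cols[ok_c]] + 1
    }
  }
  acc / pmax(wt, 1)
}

#' Predictions from a fitted V1 network
#'
#' Dispatches on `type`: `"saliency"` runs the full colour pipeline on an
#' RGB array (see [compute_saliency()]); `"responses"` returns the response
#' map of a single channel matrix; `"reconstruction"` encodes a channel and
#' reconstructs it from its own spike counts.
#'
#' @param object A fitted `"v1net"`.
#' @param newdata An H x W x 3 RGB array (for `"saliency"`) or a channel
#'   matrix.
#' @param type One of `"saliency"`, `"responses"`, `"reconstruction"`.
#' @param ... Passed on to [compute_saliency()] or [compute_response_map()].
#' @export
predict.v1net <- function(object, newdata,
                          type = c("saliency", "responses", "reconstruction"),
                          ...) {
  type <- match.arg(type)
  switch(type,
    saliency = compute_saliency(newdata, object, ...),
    responses = compute_response_map(newdata, object, ...),
    reconstruction = reconstruct(compute_response_map(newdata, object, ...),
                                 object))
}
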