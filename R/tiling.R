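# Tiled inference for rasters larger than the network input: pad, split
# into non-overlapping tile_size blocks, segment each block, splice the
# results back, crop to the original extent.

#' Tile grid geometry
#'
#' Binds a raster to its grid of square blocks: the raster is conceptually
#' zero-padded right/bottom to the least multiple of `tile_size`, then
#' covered by `n_rows` x `n_cols` non-overlapping tiles in row-major order
#' (0-based `(row, col)` indexing).
#'
#' @param height,width raster size in pixels.
#' @param tile_size block edge length (default 512).
#' @return a `tile_grid` object.
#' @export
tile_grid <- function(height, width, tile_size = 512L) {
  if (tile_size < 1L) stop("tile_size must be >= 1", call. = FALSE)
  if (height < 1L || width < 1L) stop("raster is empty", call. = FALSE)
  n_rows <- ceiling(height / tile_size)
  n_cols <- ceiling(width / tile_size)
  structure(list(
    original_height = as.integer(height), original_width = as.integer(width),
    tile_size = as.integer(tile_size),
    padded_height = as.integer(n_rows * tile_size),
    padded_width = as.integer(n_cols * tile_size),
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)
  ), class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf(
    "<tile_grid> %dx%d raster -> padded %dx%d -> %d x %d tiles of %d (%d total)\n",
    x$original_height, x$original_width, x$padded_height, x$padded_width,
    x$n_rows, x$n_cols, x$tile_size, x$n_rows * x$n_cols))
  invisible(x)
}

# pixel window (1-based, inclusive) of tile (row, col), 0-based indices
tile_window <- function(grid, row, col) {
  ts <- grid$tile_size
  list(rows = (row * ts + 1L):((row + 1L) * ts),
       cols = (col * ts + 1L):((col + 1L) * ts))
}

#' Split a raster into tiles
#'
#' Zero-pads the raster right/bottom to a multiple of `tile_size` and
#' returns the non-overlapping blocks in row-major order. Works on masks
#' (H x W) and images (H x W x C).
#'
#' @param img matrix or 3-d array.
#' @param tile_size block edge length.
#' @return list with `grid` (a [tile_grid()]) and `tiles` (list of blocks;
#'   each carries its 1-based position in attribute `tile_index`).
#' @export
split_image <- function(img, tile_size = 512L) {
  d <- dim(img)
  grid <- tile_grid(d[1], d[2], tile_size)
  has_ch <- length(d) == 3L
  padded <- if (has_ch) {
    p <- array(0L, c(grid$padded_height, grid$padded_width, d[3]))
    p[seq_len(d[1]), seq_len(d[2]), ] <- img
    p
  } else {
    p <- matrix(0L, grid$padded_height, grid$padded_width)
    p[seq_len(d[1]), seq_len(d[2])] <- img
    p
  }
  tiles <- vector("list", grid$n_rows * grid$n_cols)
  k <- 1L
  for (r in seq_len(grid$n_rows) - 1L) {
    for (cc in seq_len(grid$n_cols) - 1L) {
      w <- tile_window(grid, r, cc)
      t <- if (has_ch) padded[w$rows, w$cols, , drop = FALSE]
           else padded[w$rows, w$cols]
      attr(t, "tile_index") <- k
      tiles[[k]] <- t
      k <- k + 1L
    }
  }
  list(grid = grid, tiles = tiles)
}

#' Stitch tile masks back into a full mask
#'
#' Reassembles row-major tiles onto the padded canvas and crops to the
#' original raster extent. Tile count, per-tile shape, and (when present)
#' the `tile_index` attributes stamped by [split_image()] are audited, so a
#' permuted tile list is rejected rather than silently mis-assembled.
#'
#' @param grid a [tile_grid()].
#' @param tile_masks list of `tile_size` x `tile_size` masks, row-major.
#' @return mask matrix of the original raster size.
#' @export
stitch <- function(grid, tile_masks) {
  n <- grid$n_rows * grid$n_cols
  if (length(tile_masks) != n)
    stop(sprintf("expected %d tiles, got %d", n, length(tile_masks)),
         call. = FALSE)
  out <- matrix(0L, grid$padded_height, grid$padded_width)
  k <- 1L
  for (r in seq_len(grid$n_rows) - 1L) {
    for (cc in seq_len(grid$n_cols) - 1L) {
      t <- tile_masks[[k]]
      ti <- attr(t, "tile_index")
      if (!is.null(ti) && ti != k)
        stop(sprintf("tile order mismatch at position %d (tile_index %d)",
                     k, ti), call. = FALSE)
      if (!identical(as.integer(dim(t)[1:2]),
                     rep(grid$tile_size, 2L)))
        stop(sprintf("tile %d has shape %s, expected %dx%d", k,
                     paste(dim(t), collapse = "x"), grid$tile_size,
                     grid$tile_size), call. = FALSE)
      w <- tile_window(grid, r, cc)
      out[w$rows, w$cols] <- t
      k <- k + 1L
    }
  }
  out[seq_len(grid$original_height), seq_len(grid$original_width)]
}

#' Segment an arbitrarily large raster
#'
#' The large-farmland pipeline: split the raster into `tile_size` blocks,
#' segment each block independently, and splice the per-block masks back
#' together (no overlap or blending between blocks).
#'
#' @param img H x W x 3 image array, values 0..255.
#' @param model an [aspnet()] model, or a function `f(tile) -> mask` (e.g.
#'   an oracle predictor in tests).
#' @param tile_size block edge length; must be divisible by 16 when a
#'   network model is used.
#' @param verbose log per-stage tile counts and durations.
#' @return H x W integer mask.
#' @export
segment_large <- function(img, model, tile_size = 512L, verbose = FALSE) {
  t0 <- Sys.time()
  sp <- split_image(img, tile_size)
  t1 <- Sys.time()
  predictor <- if (is.function(model)) model else
    function(tile) predict(model, tile)
  masks <- vector("list", length(sp$tiles))
  for (k in seq_along(sp$tiles)) {
    m <- predictor(sp$tiles[[k]])
    attr(m, "tile_index") <- k
    masks[[k]] <- m
  }
  t2 <- Sys.time()
  out <- stitch(sp$grid, masks)
  if (verbose)
    message(sprintf(
      "segment_large: %d tiles (%dx%d grid) | split %.2fs, inference %.2fs, stitch %.2fs",
      length(masks), sp$grid$n_rows, sp$grid$n_cols,
      as.numeric(t1 - t0, "secs"), as.numeric(t2 - t1, "secs"),
      as.numeric(Sys.time() - t2, "secs")))
  out
}
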