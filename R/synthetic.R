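#' Synthetic ridge-scene specification
#'
#' Describes a synthetic aerial tile: green crop plots crossed by a few
#' thin, roughly parallel yellow-brown ridge stripes with optionally jittered
#' ("rough") edges, plus small bright "vacancy" patches inside the crop area
#' that act as distractors — they resemble ridge fragments but carry
#' background label 0.
#'
#' The `difficulty` presets fix the nuisance parameters: `"easy"` gives
#' straight-edged stripes with no vacancies and mild texture noise, `"hard"`
#' adds boundary jitter, vacancy distractors, and stronger noise. Any
#' explicitly supplied value overrides its preset.
#'
#' @param height,width tile size in pixels.
#' @param orientation `"vertical"`, `"horizontal"`, or `"mixed"` (each
#'   ridge's direction drawn independently with probability 1/2).
#' @param n_ridges number of ridge stripes (0 allowed: pure crop tile).
#' @param ridge_width_range integer pair, min/max stripe width in pixels;
#'   min must be >= 1 and max < min(height, width) / n_ridges so the
#'   stripes can fit without touching.
#' @param edge_roughness standard deviation (pixels) of the per-row /
#'   per-column jitter applied to each stripe boundary.
#' @param vacancy_density expected fraction of crop-area pixels covered by
#'   vacancy distractors, in `[0, 1]`.
#' @param vacancy_size_range integer pair, vacancy ellipse diameters in
#'   pixels.
#' @param background_noise_sd per-pixel Gaussian intensity noise (0..255
#'   scale) on the crop texture.
#' @param difficulty preset, `"easy"` or `"hard"`.
#' @param seed integer; identical specs (seed included) produce
#'   bit-identical scenes.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(height = 512L, width = 512L,
                       orientation = c("vertical", "horizontal", "mixed"),
                       n_ridges = 4L, ridge_width_range = c(12L, 28L),
                       edge_roughness = NULL, vacancy_density = NULL,
                       vacancy_size_range = c(4L, 10L),
                       background_noise_sd = NULL,
                       difficulty = c("easy", "hard"), seed = 1L) {
  orientation <- match.arg(orientation)
  difficulty <- match.arg(difficulty)
  preset <- if (difficulty == "easy") {
    list(edge_roughness = 0, vacancy_density = 0, background_noise_sd = 8)
  } else {
    list(edge_roughness = 2.5, vacancy_density = 0.02,
         background_noise_sd = 14)
  }
  if (is.null(edge_roughness)) edge_roughness <- preset$edge_roughness
  if (is.null(vacancy_density)) vacancy_density <- preset$vacancy_density
  if (is.null(background_noise_sd))
    background_noise_sd <- preset$background_noise_sd
  spec <- structure(list(
    height = as.integer(height), width = as.integer(width),
    orientation = orientation, n_ridges = as.integer(n_ridges),
    ridge_width_range = as.integer(ridge_width_range),
    edge_roughness = as.numeric(edge_roughness),
    vacancy_density = as.numeric(vacancy_density),
    vacancy_size_range = as.integer(vacancy_size_range),
    background_noise_sd = as.numeric(background_noise_sd),
    difficulty = difficulty, seed = as.integer(seed)
  ), class = "scene_spec")
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  with(spec, {
    if (height < 1L || width < 1L)
      stop("scene dimensions must be positive", call. = FALSE)
    if (n_ridges < 0L) stop("n_ridges must be >= 0", call. = FALSE)
    if (length(ridge_width_range) != 2L || ridge_width_range[1] < 1L ||
        ridge_width_range[2] < ridge_width_range[1])
      stop("ridge_width_range must be an increasing pair with min >= 1",
           call. = FALSE)
    if (n_ridges > 0L &&
        ridge_width_range[2] >= min(height, width) / n_ridges)
      stop(sprintf(
        paste("impossible geometry: max ridge width %d does not fit",
              "%d ridges into a %dx%d scene (need max width < %.1f)"),
        ridge_width_range[2], n_ridges, height, width,
        min(height, width) / n_ridges), call. = FALSE)
    if (edge_roughness < 0) stop("edge_roughness must be >= 0", call. = FALSE)
    if (vacancy_density < 0 || vacancy_density > 1)
      stop("vacancy_density must lie in [0, 1]", call. = FALSE)
    if (vacancy_size_range[1] < 1L ||
        vacancy_size_range[2] < vacancy_size_range[1])
      stop("vacancy_size_range must be an increasing pair >= 1",
           call. = FALSE)
  })
  invisible(spec)
}

# scene base colors (RGB, 0..255)
.ridge_rgb <- c(172, 142, 86)    # bare-soil yellow-brown
.crop_rgb <- c(66, 108, 52)      # crop green
.vacancy_rgb <- c(208, 202, 182) # small bright bare patch

# Stamp one stripe into `mask`. Stripes live in disjoint bands so that with
# roughness 0 the ridge-pixel count is exactly sum(width_i) * length.
stamp_stripe <- function(mask, band, width, roughness, vertical) {
  len <- if (vertical) nrow(mask) else ncol(mask)
  lo_max <- band[2] - width + 1L
  left <- if (lo_max > band[1]) sample(band[1]:lo_max, 1L) else band[1]
  l <- rep(left, len)
  r <- rep(left + width - 1L, len)
  if (roughness > 0) {
    l <- pmax(band[1], pmin(band[2], l + round(stats::rnorm(len, 0, roughness))))
    r <- pmax(band[1], pmin(band[2], r + round(stats::rnorm(len, 0, roughness))))
  }
  for (t in seq_len(len)) {
    if (l[t] > r[t]) next
    if (vertical) mask[t, l[t]:r[t]] <- 1L else mask[l[t]:r[t], t] <- 1L
  }
  mask
}

render_scene <- function(spec) {
  h <- spec$height; w <- spec$width
  mask <- matrix(0L, h, w)
  if (spec$n_ridges > 0L) {
    wr <- spec$ridge_width_range
    widths <- if (wr[1] == wr[2]) rep(wr[1], spec$n_ridges) else
      sample(wr[1]:wr[2], spec$n_ridges, replace = TRUE)
    vertical <- switch(spec$orientation,
      vertical = rep(TRUE, spec$n_ridges),
      horizontal = rep(FALSE, spec$n_ridges),
      mixed = stats::runif(spec$n_ridges) < 0.5)
    for (k in seq_len(spec$n_ridges)) {
      extent <- if (vertical[k]) w else h
      band <- c(floor((k - 1) * extent / spec$n_ridges) + 1L,
                floor(k * extent / spec$n_ridges))
      mask <- stamp_stripe(mask, band, widths[k], spec$edge_roughness,
                           vertical[k])
    }
  }
  vacancy <- matrix(FALSE, h, w)
  if (spec$vacancy_density > 0) {
    bg <- which(mask == 0L)
    target <- spec$vacancy_density * length(bg)
    vs <- spec$vacancy_size_range
    mean_area <- pi * mean(vs)^2 / 4
    n_vac <- max(1L, round(target / mean_area))
    cy <- arrayInd(sample(bg, n_vac, replace = TRUE), c(h, w))
    for (v in seq_len(n_vac)) {
      ax <- stats::runif(1, vs[1], vs[2]) / 2
      ay <- stats::runif(1, vs[1], vs[2]) / 2
      y0 <- cy[v, 1]; x0 <- cy[v, 2]
      ys <- max(1L, floor(y0 - ay)):min(h, ceiling(y0 + ay))
      xs <- max(1L, floor(x0 - ax)):min(w, ceiling(x0 + ax))
      inside <- outer((ys - y0)^2 / ay^2, (xs - x0)^2 / ax^2, `+`) <= 1
      # vacancies are distractors inside crop only: never touch ridge pixels
      inside <- inside & (mask[ys, xs, drop = FALSE] == 0L)
      vacancy[ys, xs] <- vacancy[ys, xs] | inside
    }
  }
  img <- array(0, c(h, w, 3))
  n_px <- h * w
  for (ch in 1:3) {
    base <- matrix(.crop_rgb[ch], h, w)
    base[mask == 1L] <- .ridge_rgb[ch]
    base[vacancy] <- .vacancy_rgb[ch]
    img[, , ch] <- base + stats::rnorm(n_px, 0, spec$background_noise_sd)
  }
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  list(image = img, mask = mask, vacancy = vacancy)
}

#' Generate one synthetic ridge scene
#'
#' Deterministic in the spec (seed included); the caller's RNG stream is
#' left untouched.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (H x W x 3 integer array, 0..255), `mask`
#'   (H x W integer matrix over \{0, 1\}, 1 = ridge), and `vacancy`
#'   (H x W logical matrix marking the distractor pixels, all labeled 0 in
#'   `mask`).
#' @export
generate_scene <- function(spec) {
  validate_scene_spec(spec)
  with_preserved_rng(spec$seed, render_scene(spec))
}

#' Generate a large synthetic scene
#'
#' Same rendering rules as [generate_scene()] at arbitrary size (for tiled
#' inference); the ridge count is scaled with the scene extent so stripe
#' density matches the template.
#'
#' @param height,width output size in pixels, both >= 512 unless
#'   `allow_small`.
#' @param spec_template a [scene_spec()] providing all non-size parameters.
#' @param allow_small permit scenes below 512 pixels (for small fixtures).
#' @return as [generate_scene()].
#' @export
generate_large_scene <- function(height, width, spec_template = scene_spec(),
                                 allow_small = FALSE) {
  if (!allow_small && (height < 512L || width < 512L))
    stop("large scenes must be at least 512x512", call. = FALSE)
  ref_extent <- if (spec_template$orientation == "horizontal")
    spec_template$height else spec_template$width
  extent <- if (spec_template$orientation == "horizontal") height else width
  n <- max(1L, as.integer(round(spec_template$n_ridges * extent / ref_extent)))
  spec <- spec_template
  spec$height <- as.integer(height)
  spec$width <- as.integer(width)
  spec$n_ridges <- n
  validate_scene_spec(spec)
  generate_scene(spec)
}

# deterministic per-tile seed stream: mix the master seed with the index
tile_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 75611) %% 2147483629)
}

#' Generate a synthetic tile dataset on disk
#'
#' Writes `n_tiles` image/mask PNG pairs plus an `index.csv` manifest and a
#' `dataset.json` metadata record under `root`. Tiles are split
#' train/validation by `split_ratio` (e.g. `c(5, 1)`); when `n_tiles` is not
#' divisible by the ratio sum the remainder tiles go to the training split.
#' Per-tile seeds are derived deterministically from `spec_template$seed`,
#' so the dataset is reproducible tile-by-tile.
#'
#' @param n_tiles number of tiles.
#' @param split_ratio integer pair `c(train, val)`.
#' @param root output directory (created if missing).
#' @param spec_template a [scene_spec()]; its height/width set the tile
#'   size, its seed is the master seed.
#' @return a `dataset_index` object: `entries` data frame (image, mask,
#'   split), `tile_size`, `split_ratio`, `root`.
#' @export
generate_dataset <- function(n_tiles, split_ratio = c(5L, 1L), root,
                             spec_template = scene_spec()) {
  if (n_tiles < 1L) stop("n_tiles must be >= 1", call. = FALSE)
  if (length(split_ratio) != 2L || any(split_ratio < 0L) ||
      sum(split_ratio) < 1L)
    stop("split_ratio must be a non-negative pair summing to >= 1",
         call. = FALSE)
  if (spec_template$height != spec_template$width)
    stop("dataset tiles must be square", call. = FALSE)
  ok <- dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root))
    stop("cannot create dataset root: ", root, call. = FALSE)
  for (d in c("images", "masks", "vacancies"))
    dir.create(file.path(root, d), showWarnings = FALSE)
  n_val <- floor(n_tiles * split_ratio[2] / sum(split_ratio))
  n_train <- n_tiles - n_val
  entries <- data.frame(
    image = character(n_tiles), mask = character(n_tiles),
    split = rep(c("train", "val"), c(n_train, n_val)),
    stringsAsFactors = FALSE)
  has_vac <- spec_template$vacancy_density > 0
  for (i in seq_len(n_tiles)) {
    spec <- spec_template
    spec$seed <- tile_seed(spec_template$seed, i)
    scene <- generate_scene(spec)
    ip <- file.path("images", sprintf("tile_%04d.png", i))
    mp <- file.path("masks", sprintf("tile_%04d_mask.png", i))
    write_image(scene$image, file.path(root, ip))
    write_mask(scene$mask, file.path(root, mp))
    if (has_vac)
      write_mask(1L * scene$vacancy,
                 file.path(root, "vacancies", sprintf("tile_%04d_vac.png", i)))
    entries$image[i] <- ip
    entries$mask[i] <- mp
  }
  utils::write.csv(entries, file.path(root, "index.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    n_tiles = n_tiles, split_ratio = as.integer(split_ratio),
    tile_size = spec_template$height, seed = spec_template$seed,
    difficulty = spec_template$difficulty
  ), file.path(root, "dataset.json"), auto_unbox = TRUE)
  dataset_index(entries, spec_template$height, as.integer(split_ratio), root)
}

dataset_index <- function(entries, tile_size, split_ratio, root) {
  structure(list(entries = entries, tile_size = as.integer(tile_size),
                 split_ratio = split_ratio, root = root),
            class = "dataset_index")
}

#' Load a dataset manifest written by [generate_dataset()]
#'
#' @param root dataset directory containing `index.csv` and `dataset.json`.
#' @return a `dataset_index`.
#' @export
read_dataset_index <- function(root) {
  ip <- file.path(root, "index.csv")
  mp <- file.path(root, "dataset.json")
  if (!file.exists(ip) || !file.exists(mp))
    stop("not a dataset directory (missing index.csv/dataset.json): ", root,
         call. = FALSE)
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  dataset_index(utils::read.csv(ip, stringsAsFactors = FALSE),
                meta$tile_size, meta$split_ratio, root)
}

#' @export
print.dataset_index <- function(x, ...) {
  cat(sprintf("<dataset_index> %d tiles (%d train / %d val), %dx%d, at %s\n",
              nrow(x$entries), sum(x$entries$split == "train"),
              sum(x$entries$split == "val"), x$tile_size, x$tile_size,
              x$root))
  invisible(x)
}

# materialize one dataset entry (paths resolved against root)
load_entry <- function(index, i) {
  e <- index$entries[i, ]
  list(image = read_image(file.path(index$root, e$image)),
       mask = read_mask(file.path(index$root, e$mask)))
}
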