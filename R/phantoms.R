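#' Construct a ground-truth lifetime scene
#'
#' A `lifetime_scene` pairs a photon-count intensity image with a per-pixel
#' lifetime image (ns) and a boolean foreground mask. Background pixels carry
#' exactly zero intensity and zero lifetime.
#'
#' @param intensity `side x side` nonnegative matrix of photon counts.
#' @param lifetime `side x side` matrix of lifetimes (ns), 0 on background.
#' @param mask logical `side x side` foreground indicator; default `intensity > 0`.
#' @param scene_id opaque identifier string.
#' @param level photon-level tag: `"1"`, `"2"`, `"3"` or `"full"`.
#' @return object of class `lifetime_scene`.
#' @export
lifetime_scene <- function(intensity, lifetime, mask = NULL,
                           scene_id = "scene", level = "full") {
  assert_matrix(intensity, "intensity")
  assert_matrix(lifetime, "lifetime", dims = dim(intensity))
  if (any(intensity < 0)) stop("intensity must be nonnegative")
  mask <- mask %||% (intensity > 0)
  if (!is.logical(mask) || !all(dim(mask) == dim(intensity)))
    stop("mask must be a logical matrix matching intensity")
  if (any(intensity[!mask] != 0)) stop("background pixels must have zero intensity")
  if (any(lifetime[!mask] != 0)) stop("background pixels must have zero lifetime")
  structure(list(intensity = intensity, lifetime = lifetime, mask = mask,
                 scene_id = scene_id, level = as.character(level)),
            class = "lifetime_scene")
}

#' @export
print.lifetime_scene <- function(x, ...) {
  cat(sprintf("<lifetime_scene> %s: %dx%d, %d fg px, max %g counts, tau %s ns, level %s\n",
              x$scene_id, nrow(x$intensity), ncol(x$intensity), sum(x$mask),
              max(x$intensity),
              if (any(x$mask)) paste(signif(range(x$lifetime[x$mask]), 3), collapse = "-")
              else "-", x$level))
  invisible(x)
}

photon_level_range <- function(level) {
  switch(as.character(level),
         "1" = c(25, 100), "2" = c(100, 400), "3" = c(400, 1600),
         "full" = c(25, 1600),
         stop("unknown photon level tag: ", level))
}

# distance from each grid point to a polyline (min over segments)
dist_to_polyline <- function(px, py, xs, ys) {
  d <- rep(Inf, length(px))
  for (s in seq_len(length(xs) - 1L)) {
    ax <- xs[s]; ay <- ys[s]; bx <- xs[s + 1L]; by <- ys[s + 1L]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d <- pmin(d, sqrt(dx * dx + dy * dy))
  }
  d
}

draw_stroke <- function(w, h) {
  type <- sample(c("segment", "polyline", "arc", "bar"), 1)
  m <- 2.5
  rxy <- function() c(stats::runif(1, m, w - m), stats::runif(1, m, h - m))
  if (type == "segment") {
    a <- rxy(); b <- rxy()
    xs <- c(a[1], b[1]); ys <- c(a[2], b[2])
  } else if (type == "polyline") {
    a <- rxy(); b <- rxy(); cpt <- rxy()
    xs <- c(a[1], cpt[1], b[1]); ys <- c(a[2], cpt[2], b[2])
  } else if (type == "arc") {
    ctr <- c(stats::runif(1, w * 0.3, w * 0.7), stats::runif(1, h * 0.3, h * 0.7))
    r <- stats::runif(2, min(w, h) * 0.15, min(w, h) * 0.42)
    th0 <- stats::runif(1, 0, 2 * pi)
    th <- th0 + seq(0, stats::runif(1, pi, 2 * pi), length.out = 24)
    xs <- ctr[1] + r[1] * cos(th); ys <- ctr[2] + r[2] * sin(th)
  } else { # bar: short thick segment
    a <- rxy(); ang <- stats::runif(1, 0, pi); len <- stats::runif(1, 3, 8)
    xs <- c(a[1], a[1] + len * cos(ang)); ys <- c(a[2], a[2] + len * sin(ang))
  }
  list(xs = xs, ys = ys,
       thick = stats::runif(1, 1.0, if (type == "bar") 3.0 else 2.2))
}

#' Procedurally draw a glyph-like grayscale image
#'
#' Draws 1-3 random strokes (segments, polylines, elliptical arcs, bars) with
#' a smooth quadratic falloff profile on a `canvas` grid, emulating the
#' handwritten digit/letter shapes used as raw material for lifetime phantoms.
#' Deterministic in `shape_seed`; the stroke parameters are resampled (with a
#' derived seed) until the nonzero fraction lies in [0.05, 0.6].
#'
#' @param shape_seed integer seed.
#' @param canvas integer pair, canvas height/width (>= 8 each).
#' @return `canvas` matrix with values in [0, 1], max exactly 1.
#' @export
make_glyph <- function(shape_seed, canvas = c(28L, 28L)) {
  if (length(canvas) == 1L) canvas <- c(canvas, canvas)
  if (any(canvas < 8)) stop("canvas too small: need at least 8x8")
  h <- as.integer(canvas[1]); w <- as.integer(canvas[2])
  grid <- expand.grid(py = seq_len(h), px = seq_len(w))
  for (attempt in 0:19) {
    att_seed <- as.integer((as.numeric(shape_seed) + attempt * 1000003) %%
                             (.Machine$integer.max - 1)) + 1L
    g <- with_seed(att_seed, {
      img <- matrix(0, h, w)
      for (s in seq_len(sample(1:3, 1))) {
        st <- draw_stroke(w, h)
        d <- dist_to_polyline(grid$px, grid$py, st$xs, st$ys)
        # saturated core with a narrow soft edge, like a pen stroke
        val <- pmin(1, 1.6 * pmax(0, 1 - (d / st$thick)^2))
        img <- pmax(img, matrix(val, h, w))
      }
      img[img < 0.05] <- 0
      img
    })
    frac <- mean(g > 0)
    if (frac >= 0.05 && frac <= 0.6 && max(g) > 0) return(g / max(g))
  }
  # deterministic fallback: a plain diagonal stroke always inside bounds
  d <- dist_to_polyline(grid$px, grid$py, c(4, w - 4), c(4, h - 4))
  g <- matrix(pmax(0, 1 - (d / 1.8)^2), h, w)
  g / max(g)
}

#' Read images from an IDX (idx3-ubyte) file
#'
#' Minimal reader for the IDX image container used by MNIST-family datasets,
#' so real handwritten-glyph banks can replace the procedural generator.
#'
#' @param path file path.
#' @param max_images cap on images read.
#' @return list of matrices with values in [0, 1].
#' @export
read_idx_images <- function(path, max_images = Inf) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, 2051L))
    stop(sprintf("malformed IDX file: expected magic 2051 at offset 0, got %d", magic))
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  h <- readBin(con, "integer", 1, size = 4, endian = "big")
  w <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (any(c(n, h, w) <= 0))
    stop("malformed IDX file: nonpositive dimension in header (offsets 4-15)")
  n <- min(n, max_images)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    px <- readBin(con, "integer", h * w, size = 1, signed = FALSE)
    if (length(px) < h * w)
      stop(sprintf("malformed IDX file: truncated pixel data at offset %d",
                   16 + (i - 1) * h * w + length(px)))
    out[[i]] <- matrix(px, h, w, byrow = TRUE) / 255
  }
  out
}

# Rotate a glyph by `angle` degrees about its center (nearest neighbour,
# inverse mapping) onto a canvas of the same size.
rotate_glyph <- function(g, angle) {
  h <- nrow(g); w <- ncol(g)
  if (angle %% 360 == 0) return(g)
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  grid <- expand.grid(y = seq_len(h), x = seq_len(w))
  # inverse rotation of output coords into input coords
  sy <- cy + cos(th) * (grid$y - cy) + sin(th) * (grid$x - cx)
  sx <- cx - sin(th) * (grid$y - cy) + cos(th) * (grid$x - cx)
  iy <- round(sy); ix <- round(sx)
  ok <- iy >= 1 & iy <= h & ix >= 1 & ix <= w
  out <- numeric(h * w)
  out[ok] <- g[cbind(iy[ok], ix[ok])]
  matrix(out, h, w)
}

#' Compose a ground-truth scene from glyph images
#'
#' Each glyph is rotated by a random multiple of 90 degrees plus a small
#' random angle (uniform on -15..15 degrees, nearest-neighbour resampling,
#' re-thresholded at 0.1), placed at a random offset in the `side x side`
#' frame, scaled so its maximum pixel intensity is drawn uniformly from the
#' photon level's range, and assigned a single lifetime drawn uniformly from
#' 0.3-1.5 ns (one dye per glyph). Overlaps sum intensities and
#' intensity-weight-average lifetimes; the summed image is clipped at the
#' level maximum.
#'
#' @param glyphs list of 1-3 grayscale glyph matrices (values in [0, 1]).
#' @param level photon level tag `"1"|"2"|"3"|"full"` (max CW intensity in
#'   25-100, 100-400, 400-1600 or 25-1600 counts).
#' @param rng_seed integer seed.
#' @param side output frame side (default 32).
#' @param per_pixel_lifetime if `TRUE`, draw an independent lifetime per pixel
#'   instead of one per glyph.
#' @return a [lifetime_scene()].
#' @export
make_scene <- function(glyphs, level = "full", rng_seed = 1L, side = 32L,
                       per_pixel_lifetime = FALSE) {
  if (is.matrix(glyphs)) glyphs <- list(glyphs)
  if (length(glyphs) < 1) stop("need at least one glyph")
  if (length(glyphs) > 3) stop("at most 3 glyphs per scene")
  rng <- photon_level_range(level)  # validates the tag
  side <- as.integer(side)
  for (g in glyphs) {
    if (!is.matrix(g) || any(dim(g) > side))
      stop("each glyph must be a matrix fitting the ", side, "x", side, " frame")
  }
  with_seed(rng_seed, {
    I <- matrix(0, side, side)
    Tnum <- matrix(0, side, side)
    n_hit <- matrix(0L, side, side)
    tau_last <- matrix(0, side, side)
    for (g in glyphs) {
      ang <- sample(c(0, 90, 180, 270), 1) + stats::runif(1, -15, 15)
      gr <- rotate_glyph(g, ang)
      gr[gr < 0.1] <- 0
      if (all(gr == 0)) gr <- g  # degenerate rotation: keep the original
      placed <- matrix(0, side, side)
      oy <- sample.int(side - nrow(gr) + 1L, 1) - 1L
      ox <- sample.int(side - ncol(gr) + 1L, 1) - 1L
      placed[oy + seq_len(nrow(gr)), ox + seq_len(ncol(gr))] <- gr
      peak <- stats::runif(1, rng[1], rng[2])
      placed <- placed * (peak / max(placed))
      tau <- if (per_pixel_lifetime)
        matrix(stats::runif(side * side, 0.3, 1.5), side, side)
      else stats::runif(1, 0.3, 1.5)
      I <- I + placed
      Tnum <- Tnum + placed * tau
      hit <- placed > 0
      n_hit <- n_hit + hit
      if (per_pixel_lifetime) tau_last[hit] <- tau[hit] else tau_last[hit] <- tau
    }
    tau_img <- matrix(0, side, side)
    fg <- I > 0
    tau_img[fg] <- Tnum[fg] / I[fg]
    # pixels touched by a single glyph carry that glyph's lifetime exactly
    one <- n_hit == 1L
    tau_img[one] <- tau_last[one]
    I[I > rng[2]] <- rng[2]
    lifetime_scene(I, tau_img, mask = fg,
                   scene_id = sprintf("scene_%d", as.integer(rng_seed)),
                   level = level)
  })
}

#' Generate a reproducible dataset of scenes
#'
#' Draws per-scene glyph and composition seeds from split-specific seed
#' streams, so `train`, `val` and `test` sequences generated from the same
#' `rng_seed` never share a scene.
#'
#' @param n number of scenes (>= 1).
#' @param split `"train"`, `"val"` or `"test"`.
#' @param level photon level tag for all scenes, or `"mix"` to stratify
#'   uniformly over levels 1-3.
#' @param rng_seed integer master seed.
#' @param side frame side.
#' @return list of [lifetime_scene()] objects, length `n`.
#' @export
make_dataset <- function(n, split = c("train", "val", "test"),
                         level = "full", rng_seed = 1L, side = 32L) {
  split <- match.arg(split)
  if (n < 1) stop("`n` must be >= 1")
  split_seed <- as.integer((as.numeric(rng_seed) * 97 +
                            match(split, c("train", "val", "test")) * 1000003) %%
                           (.Machine$integer.max - 1)) + 1L
  seeds <- with_seed(split_seed, {
    matrix(sample.int(.Machine$integer.max - 1L, 5L * n), nrow = n)
  })
  lapply(seq_len(n), function(i) {
    n_glyph <- 1L + (seeds[i, 1] %% 3L)
    glyphs <- lapply(seq_len(n_glyph), function(j) make_glyph(seeds[i, 1 + j]))
    lev <- if (identical(level, "mix")) as.character(1L + (seeds[i, 5] %% 3L)) else level
    sc <- make_scene(glyphs, level = lev, rng_seed = seeds[i, 5], side = side)
    sc$scene_id <- sprintf("%s_%05d", split, i)
    sc
  })
}
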