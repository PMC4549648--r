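#' @keywords internal
#' @importFrom stats rpois rnorm
"_PACKAGE"

# Internal helpers shared across modules. Conventions (fixed for the whole
# package): frames indexed from 0 in time units (t_s = (frame-1) * frame_interval
# for R's 1-based frame index), pixels 0-based row-major with physical position
# index * pixel_size at pixel centers, positions are (x, y) in micrometers.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded simulation code does not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derived from a master seed and a text tag; always in
# [1, 2^31 - 2] so it is a valid 32-bit R seed.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) %% 99991L
  as.integer((as.double(seed) * 1009 + h) %% 2147483646 + 1)
}

# Centered moving average with shrinking windows at the ends; width k is
# forced odd. NAs propagate unless na.rm.
moving_average <- function(x, k, na.rm = FALSE) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    out[i] <- mean(x[j], na.rm = na.rm)
  }
  out
}

# Bilinear interpolation of a matrix at continuous pixel coordinates.
# x = column coordinate, y = row coordinate, both 0-based at pixel centers.
# Coordinates are clamped to the image border.
bilinear_weights <- function(x, y, H, W) {
  x <- clamp(x, 0, W - 1)
  y <- clamp(y, 0, H - 1)
  x0 <- pmin(floor(x), W - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(y), H - 2); y0 <- pmax(y0, 0)
  fx <- x - x0
  fy <- y - y0
  # linear indices (1-based, column-major H x W)
  i00 <- (y0 + 1) + x0 * H
  list(
    idx = cbind(i00, i00 + 1, i00 + H, i00 + H + 1),
    w   = cbind((1 - fx) * (1 - fy), (1 - fx) * fy, fx * (1 - fy), fx * fy)
  )
}

bilinear_sample <- function(mat, x, y) {
  bw <- bilinear_weights(x, y, nrow(mat), ncol(mat))
  v <- mat[bw$idx[, 1]] * bw$w[, 1] + mat[bw$idx[, 2]] * bw$w[, 2] +
    mat[bw$idx[, 3]] * bw$w[, 3] + mat[bw$idx[, 4]] * bw$w[, 4]
  v
}

# Sample every frame of a T x H x W stack at fixed continuous points.
# Returns a T x n matrix. Uses matrix-index gathers to avoid copying the
# (possibly large) stack.
bilinear_sample_stack <- function(stack, x, y) {
  d <- dim(stack)
  Tn <- d[1]; H <- d[2]; W <- d[3]
  bw <- bilinear_weights(x, y, H, W)
  n <- length(x)
  tt <- rep.int(seq_len(Tn), n)
  out <- matrix(0, Tn, n)
  for (j in 1:4) {
    li <- bw$idx[, j] - 1L            # 0-based H*W linear index
    rows <- (li %% H) + 1L
    cols <- (li %/% H) + 1L
    v <- stack[cbind(tt, rep(rows, each = Tn), rep(cols, each = Tn))]
    out <- out + matrix(v, Tn, n) * rep(bw$w[, j], each = Tn)
  }
  out
}

# Gather a fixed pixel subset (linear H*W indices) from every frame of a
# T x H x W stack without copying it; returns a T x n matrix.
gather_pixels <- function(stack, idx) {
  d <- dim(stack)
  Tn <- d[1]; H <- d[2]
  li <- idx - 1L
  rows <- (li %% H) + 1L
  cols <- (li %/% H) + 1L
  tt <- rep.int(seq_len(Tn), length(idx))
  matrix(stack[cbind(tt, rep(rows, each = Tn), rep(cols, each = Tn))],
         Tn, length(idx))
}

# Pixel-center coordinate grids in micrometers for an H x W image.
coord_grids <- function(H, W, pixel_size) {
  X <- matrix(rep((seq_len(W) - 1) * pixel_size, each = H), H, W)
  Y <- matrix(rep((seq_len(H) - 1) * pixel_size, times = W), H, W)
  list(X = X, Y = Y)
}

# Connected-component utilities on binary H x W matrices, 4-connectivity.
# BFS flood fill from seed indices; returns logical matrix of reached pixels.
flood_from <- function(fg, seeds) {
  H <- nrow(fg); W <- ncol(fg)
  visited <- logical(H * W)
  fgv <- as.logical(fg)
  frontier <- seeds[fgv[seeds] & !visited[seeds]]
  visited[frontier] <- TRUE
  while (length(frontier)) {
    row <- (frontier - 1L) %% H
    up    <- frontier[row > 0L] - 1L
    down  <- frontier[row < (H - 1L)] + 1L
    left  <- frontier[frontier > H] - H
    right <- frontier[frontier <= H * (W - 1L)] + H
    nb <- c(up, down, left, right)
    nb <- unique(nb[fgv[nb] & !visited[nb]])
    visited[nb] <- TRUE
    frontier <- nb
  }
  matrix(visited, H, W)
}

# Largest connected component of a binary matrix (4-connectivity). Repeatedly
# floods from the first unassigned foreground pixel; cells are typically a
# single blob so one pass is the common case.
largest_component <- function(fg) {
  remaining <- fg
  best <- NULL
  best_n <- 0L
  while (any(remaining)) {
    seed <- which(remaining)[1L]
    comp <- flood_from(remaining, seed)
    n <- sum(comp)
    if (n > best_n) {
      best <- comp
      best_n <- n
    }
    remaining <- remaining & !comp
  }
  if (is.null(best)) fg else best
}

# Fill holes: background regions not connected to the image border.
fill_holes <- function(fg) {
  H <- nrow(fg); W <- ncol(fg)
  bg <- !fg
  border <- unique(c(
    seq_len(H), (W - 1L) * H + seq_len(H),
    (seq_len(W) - 1L) * H + 1L, (seq_len(W) - 1L) * H + H
  ))
  outside <- flood_from(bg, border)
  fg | (bg & !outside)
}

# Strict JSON writers used for sidecars/reports: stable key order, no
# scientific notation surprises, unboxed scalars.
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
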