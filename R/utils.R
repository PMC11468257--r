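# Voxel-grid helpers shared by segmentation and feature extraction.

# Neighbourhood offset matrix (n x 3) for 6-, 18- or 26-connectivity.
connectivity_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1L,
                 "18" = nz >= 1L & nz <= 2L,
                 "26" = nz >= 1L,
                 stop("connectivity must be 6, 18 or 26", call. = FALSE))
  unname(g[keep, , drop = FALSE])
}

# Connected component of `mask` (logical 3-D array) containing seed index
# (length-3, 1-based). Breadth-first flood fill over the chosen neighbourhood.
connected_component <- function(mask, seed, connectivity = 26L) {
  d <- dim(mask)
  if (!mask[seed[1], seed[2], seed[3]]) {
    stop("seed voxel is not inside the mask", call. = FALSE)
  }
  offs <- connectivity_offsets(connectivity)
  comp <- array(FALSE, dim = d)
  comp[seed[1], seed[2], seed[3]] <- TRUE
  frontier <- matrix(as.integer(seed), ncol = 3L)
  while (nrow(frontier) > 0L) {
    cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), , drop = FALSE] +
      offs[rep(seq_len(nrow(offs)), times = nrow(frontier)), , drop = FALSE]
    ok <- cand[, 1] >= 1L & cand[, 1] <= d[1] &
      cand[, 2] >= 1L & cand[, 2] <= d[2] &
      cand[, 3] >= 1L & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) break
    lin <- cand[, 1] + (cand[, 2] - 1L) * d[1] + (cand[, 3] - 1L) * d[1] * d[2]
    keep <- mask[lin] & !comp[lin]
    lin <- unique(lin[keep])
    if (length(lin) == 0L) break
    comp[lin] <- TRUE
    frontier <- cbind((lin - 1L) %% d[1] + 1L,
                      ((lin - 1L) %/% d[1]) %% d[2] + 1L,
                      (lin - 1L) %/% (d[1] * d[2]) + 1L)
  }
  comp
}

# Logical array marking mask voxels with at least one face-adjacent (6-conn)
# neighbour outside the mask; the array border counts as outside. Computed by
# shifted-array comparison, no loops over voxels.
boundary_voxels <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, dim = d)
  shift_covered <- function(ax, by) {
    out <- array(FALSE, dim = d)
    n <- d[ax]
    idx_to <- vector("list", 3L); idx_from <- vector("list", 3L)
    for (a in 1:3) idx_to[[a]] <- idx_from[[a]] <- seq_len(d[a])
    if (by == 1L) { idx_to[[ax]] <- 2:n; idx_from[[ax]] <- 1:(n - 1L) }
    else { idx_to[[ax]] <- 1:(n - 1L); idx_from[[ax]] <- 2:n }
    out[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
      mask[idx_from[[1]], idx_from[[2]], idx_from[[3]]]
    out
  }
  for (ax in 1:3) {
    if (d[ax] < 2L) { interior[] <- FALSE; next }
    interior <- interior & shift_covered(ax, 1L) & shift_covered(ax, -1L)
    # faces at the array border have an implicit outside neighbour
    idx <- vector("list", 3L); for (a in 1:3) idx[[a]] <- seq_len(d[a])
    idx[[ax]] <- c(1L, d[ax])
    interior[idx[[1]], idx[[2]], idx[[3]]] <- FALSE
  }
  mask & !interior
}

# Minimum Euclidean distance (mm) from each row of `points` (n x 3, world mm)
# to the world centres of the TRUE voxels in `coords` (m x 3). Chunked so the
# temporary n*m matrix stays small.
min_dist_to_points <- function(points, coords, chunk = 2e6) {
  n <- nrow(points); m <- nrow(coords)
  if (m == 0L) stop("empty coordinate set", call. = FALSE)
  out <- numeric(n)
  rows_per_chunk <- max(1L, floor(chunk / m))
  for (start in seq(1L, n, by = rows_per_chunk)) {
    end <- min(n, start + rows_per_chunk - 1L)
    p <- points[start:end, , drop = FALSE]
    d2 <- outer(p[, 1], coords[, 1], `-`)^2 +
      outer(p[, 2], coords[, 2], `-`)^2 +
      outer(p[, 3], coords[, 3], `-`)^2
    out[start:end] <- sqrt(apply(d2, 1L, min))
  }
  out
}

# Exact anisotropic squared Euclidean distance transform (lower-envelope
# algorithm), one 1-D pass per axis. `f` holds squared distances so far; `w2`
# is the squared voxel spacing along the axis being swept.
dt1d_squared <- function(f, w2) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0L || n == 1L) return(f)
  if (length(fin) < n) {
    # infinite entries carry no parabola; evaluate directly over the finite
    # support (short lines, only hit where whole planes are empty)
    d <- numeric(n)
    for (i in seq_len(n)) d[i] <- min(f[fin] + w2 * (i - fin)^2)
    return(d)
  }
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + w2 * q^2) - (f[v[k]] + w2 * v[k]^2)) / (2 * w2 * (q - v[k]))
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + w2 * q^2) - (f[v[k]] + w2 * v[k]^2)) / (2 * w2 * (q - v[k]))
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  d <- numeric(n); k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- w2 * (q - v[k])^2 + f[v[k]]
  }
  d
}

# Euclidean distance (mm) from every voxel centre to the nearest TRUE voxel
# centre of `mask`. Exact (up to fp rounding of sums of squares).
distance_to_mask_mm <- function(mask, spacing) {
  d <- dim(mask)
  f <- array(ifelse(mask, 0, Inf), dim = d)
  for (ax in 1:3) {
    w2 <- spacing[ax]^2
    if (d[ax] > 1L) {
      f <- apply(f, setdiff(1:3, ax), dt1d_squared, w2 = w2)
      # apply() puts the swept axis first; restore the original order
      perm <- order(c(ax, setdiff(1:3, ax)))
      f <- aperm(array(f, dim = c(d[ax], d[setdiff(1:3, ax)])), perm)
    }
  }
  sqrt(f)
}

# Parse a plain-text "key = value" config file into a named character vector.
# '#' starts a comment; blank lines ignored; values keep internal whitespace.
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  stats::setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
}
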