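# Independent oracles and fixture builders. These deliberately avoid the
# package's own implementations: the flood fill is a plain BFS, the
# confusion counts a double loop, the sector test an analytic formula.

# analytic sector membership (apex top-centre, 120 degrees, inscribed radius)
oracle_in_sector <- function(r, c, width, height) {
  apex_r <- 1; apex_c <- (width + 1) / 2
  radius <- min(height - 1, (width - 1) / (2 * sin(pi / 3)))
  dr <- r - apex_r; dc <- c - apex_c
  rho <- sqrt(dr^2 + dc^2)
  rho <= radius && (rho == 0 || atan2(abs(dc), dr) <= pi / 3 + 1e-12)
}

oracle_sector_mask <- function(width, height) {
  m <- matrix(FALSE, height, width)
  for (r in seq_len(height)) for (c in seq_len(width))
    m[r, c] <- oracle_in_sector(r, c, width, height)
  m
}

# brute-force fill of a gap-free closed curve: BFS (4-connectivity) over
# non-curve pixels from every raster border pixel; mask = unreached pixels
# (interior plus curve), then cropped to the sector
oracle_fill <- function(curve_coords, dims) {
  h <- dims[1]; w <- dims[2]
  curve <- matrix(FALSE, h, w); curve[curve_coords] <- TRUE
  visited <- matrix(FALSE, h, w)
  queue <- which(matrix(row(matrix(0, h, w)) %in% c(1, h) |
                          col(matrix(0, h, w)) %in% c(1, w), h, w) & !curve)
  visited[queue] <- TRUE
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    r <- (p - 1) %% h + 1; c <- (p - 1) %/% h + 1
    for (d in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))) {
      if (d[1] < 1 || d[1] > h || d[2] < 1 || d[2] > w) next
      q <- (d[2] - 1) * h + d[1]
      if (!visited[q] && !curve[q]) { visited[q] <- TRUE; queue <- c(queue, q) }
    }
  }
  (!visited) & oracle_sector_mask(w, h)
}

# exhaustive pixel-loop confusion counts over an evaluable region
oracle_confusion <- function(reference, test, region) {
  tp <- tn <- fp <- fn <- 0L
  for (r in seq_len(nrow(reference))) for (c in seq_len(ncol(reference))) {
    if (!region[r, c]) next
    if (reference[r, c] && test[r, c]) tp <- tp + 1L
    else if (reference[r, c]) fn <- fn + 1L
    else if (test[r, c]) fp <- fp + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# inner 4-boundary of a mask (the curve a tracer would draw around it)
boundary_of <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c]) next
    nb <- c(r > 1 && mask[r - 1, c], r < h && mask[r + 1, c],
            c > 1 && mask[r, c - 1], c < w && mask[r, c + 1])
    if (!all(nb)) out[r, c] <- TRUE
  }
  out
}

# smooth star-shaped blob mask, fully inside the sector of a 96-wide x
# 64-high raster when centred near (30, 48) with r0 <= 12
random_blob <- function(dims, center, r0, seed) {
  set.seed(seed)
  ph <- runif(2, 0, 2 * pi)
  a2 <- runif(1, 0, 0.25); a3 <- runif(1, 0, 0.15)
  h <- dims[1]; w <- dims[2]
  rr <- matrix(seq_len(h), h, w) - center[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - center[2]
  th <- atan2(cc, rr)
  rad <- r0 * (1 + a2 * sin(2 * th + ph[1]) + a3 * sin(3 * th + ph[2]))
  sqrt(rr^2 + cc^2) <= rad
}

random_mask <- function(dims, p, seed) {
  set.seed(seed)
  matrix(runif(prod(dims)) < p, dims[1], dims[2])
}

# compact phantom configuration used across tests
test_config <- function(...) phantom_config(128, 96, ...)
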