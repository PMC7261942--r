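# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately share no code with the package internals:
# dice by explicit set counting, components by recursive flood fill, patch
# pooling by double loop, region matching by an exhaustive overlap matrix.

oracle_dice <- function(pred, ref) {
  p <- which(pred != 0)
  r <- which(ref != 0)
  if (length(p) + length(r) == 0) return(1)
  2 * length(intersect(p, r)) / (length(p) + length(r))
}

# flood fill, 8-connectivity, pure R
oracle_components_2d <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue) > 0) {
      q <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ni <- q[1] + di; nj <- q[2] + dj
        if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
        if (mask[ni, nj] != 0 && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cur
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

oracle_patch <- function(mask, edge) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, ceiling(nr / edge), ceiling(nc / edge))
  for (bi in seq_len(nrow(out))) for (bj in seq_len(ncol(out))) {
    rows <- ((bi - 1) * edge + 1):min(bi * edge, nr)
    cols <- ((bj - 1) * edge + 1):min(bj * edge, nc)
    out[bi, bj] <- as.integer(any(mask[rows, cols] != 0))
  }
  out
}

# lesion-level counts by exhaustive per-component overlap checks
# (any-overlap rule: a ref component is hit if any pred pixel lies on it)
oracle_region_counts <- function(pred, ref) {
  lp <- oracle_components_2d(pred)
  lr <- oracle_components_2d(ref)
  np <- max(lp); nref <- max(lr)
  if (np == 0 && nref == 0) {
    return(list(tp = 0L, fp = 0L, fn = 0L, empty = TRUE))
  }
  tp <- sum(vapply(seq_len(nref), function(b) any(lr == b & pred != 0),
                   logical(1)))
  fp <- sum(vapply(seq_len(np), function(a) !any(lp == a & ref != 0),
                   logical(1)))
  list(tp = as.integer(tp), fp = as.integer(fp),
       fn = as.integer(nref - tp), empty = FALSE)
}

random_mask <- function(nr, nc, p = 0.25) {
  matrix(rbinom(nr * nc, 1, p), nr, nc)
}

random_mask_3d <- function(ns, nr, nc, p = 0.2) {
  array(rbinom(ns * nr * nc, 1, p), c(ns, nr, nc))
}

as_mask <- function(values, class = "WMH", in_plane = 1, slice = 7) {
  if (length(dim(values)) == 2L) values <- array(values, c(1, dim(values)))
  lesion_mask(values, class, in_plane, slice)
}

# small single-class phantom configuration used in several tests
tiny_config <- function(seed, classes_on = csvd_classes(), noise_sd = 5,
                        grid = c(8L, 64L, 64L)) {
  counts <- lapply(csvd_classes(), function(cls) {
    if (cls %in% classes_on) c(1L, 2L) else c(0L, 0L)
  })
  names(counts) <- csvd_classes()
  phantom_config(grid_shape = grid, in_plane_spacing_range = c(1, 1),
                 noise_sd = noise_sd, seed = seed, lesion_counts = counts)
}
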