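# Independent oracles, deliberately naive: plain-R flood fill,
# per-pixel tallies, and explicit edge enumeration. They never touch
# the package's C++ path.

# iterative flood fill over a logical mask
oracle_label <- function(mask, connectivity = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbrs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(queue) > 0) {
      rc <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (d in nbrs) {
        rr <- rc[1] + d[1]; cc <- rc[2] + d[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# exposed-edge count of the patch containing pixels where lab == id,
# by looping over every pixel edge
oracle_perimeter_edges <- function(lab, id) {
  nr <- nrow(lab); nc <- ncol(lab)
  edges <- 0L
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    if (lab[r, c] != id) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      outside <- rr < 1 || rr > nr || cc < 1 || cc > nc
      if (outside || lab[rr, cc] != id) edges <- edges + 1L
    }
  }
  edges
}

# random legend-coded raster (no nodata unless asked)
random_raster <- function(nr = 50, nc = 50, pixel_size = 25,
                          codes = 1:4, nodata_frac = 0) {
  g <- matrix(sample(codes, nr * nc, replace = TRUE), nr, nc)
  if (nodata_frac > 0) {
    k <- round(nodata_frac * nr * nc)
    g[sample(nr * nc, k)] <- 0L
  }
  lc_raster(g, pixel_size = pixel_size)
}

# one fixture unit of a given group, shrunk for fast tests
small_unit <- function(group, area_ha = 60) {
  fx <- build_study_fixture()
  u <- fx[fx$group == group, ][1, ]
  u$total_area <- area_ha * 1e4
  u
}

# scenario config over a shrunken fixture for fast end-to-end tests
small_fixture <- function(area_ha = 60) {
  fx <- build_study_fixture()
  fx$total_area <- rep(area_ha * 1e4, 31)
  fx
}
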