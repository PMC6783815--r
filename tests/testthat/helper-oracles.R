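# Independent oracles used across the suite.

# Brute-force 3D hull vertex oracle: a triple of points spans a hull facet
# iff all points lie (weakly) on one side of its plane; hull vertices are
# the union of facet triples. O(n^3) plane tests, vectorized per triple.
brute_force_hull_vertices <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  cmb <- utils::combn(n, 3)
  a <- pts[cmb[1, ], , drop = FALSE]
  b <- pts[cmb[2, ], , drop = FALSE]
  c_ <- pts[cmb[3, ], , drop = FALSE]
  u <- b - a; w <- c_ - a
  nn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  d <- nn %*% t(pts) - rowSums(nn * a)  # triples x points signed offsets
  onesided <- (rowSums(d > tol) == 0L) | (rowSums(d < -tol) == 0L)
  sort(unique(as.vector(cmb[, onesided])))
}

# Breadth-first connected-component labeling oracle on a logical 3D array.
bfs_components <- function(arr, connectivity = 26L) {
  d <- dim(arr)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   `6` = 1, `18` = 2, `26` = 3), ,
               drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  idx <- which(arr)
  for (s in idx) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      v0 <- v - 1L
      z <- v0 %% d[1]; r <- v0 %/% d[1]; y <- r %% d[2]; x <- r %/% d[2]
      for (k in seq_len(nrow(offs))) {
        zz <- z + offs[k, 1]; yy <- y + offs[k, 2]; xx <- x + offs[k, 3]
        if (zz < 0 || zz >= d[1] || yy < 0 || yy >= d[2] ||
            xx < 0 || xx >= d[3]) next
        w <- 1L + zz + d[1] * (yy + d[2] * xx)
        if (arr[w] && lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  lab
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# small solid cube mask centered in an n^3 grid
cube_mask <- function(side, pad = 3L) {
  n <- side + 2L * pad
  a <- array(FALSE, c(n, n, n))
  a[pad + seq_len(side), pad + seq_len(side), pad + seq_len(side)] <- TRUE
  a
}
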