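# Independent oracles used across the suite. These are deliberately naive
# (double loops, per-pixel scans) so they share no code path with the
# implementation they check.

# brute-force box count: loop over every box and every pixel in it
brute_box_count <- function(px, mask, eps) {
  nr <- nrow(px); nc <- ncol(px)
  n <- 0L
  for (br in seq_len(ceiling(nr / eps))) {
    for (bc in seq_len(ceiling(nc / eps))) {
      rows <- ((br - 1) * eps + 1):min(br * eps, nr)
      cols <- ((bc - 1) * eps + 1):min(bc * eps, nc)
      hit <- FALSE
      for (r in rows) {
        for (c in cols) {
          if (px[r, c] && mask[r, c]) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit) n <- n + 1L
    }
  }
  n
}

# brute-force annulus membership by per-pixel distance check
brute_annulus <- function(n, mm_per_px, inner_mm, outer_mm,
                          center = c((n + 1) / 2, (n + 1) / 2)) {
  m <- matrix(FALSE, n, n)
  r_in <- inner_mm / 2 / mm_per_px
  r_out <- outer_mm / 2 / mm_per_px
  for (r in seq_len(n)) {
    for (c in seq_len(n)) {
      d <- sqrt((r - center[1])^2 + (c - center[2])^2)
      if (d >= r_in && d < r_out) m[r, c] <- TRUE
    }
  }
  m
}

# heteroskedasticity-robust OLS (HC0) for the singleton-cluster GEE oracle
ols_hc0 <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  r <- drop(y - X %*% beta)
  meat <- crossprod(X * r)
  bread <- solve(crossprod(X))
  list(coefficients = drop(beta), vcov = bread %*% meat %*% bread)
}

# small random blobby binary image for property tests
random_blob_map <- function(n = 64, n_blobs = 12, seed = 1) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  for (k in seq_len(n_blobs)) {
    r <- sample(3:(n - 2), 1); c <- sample(3:(n - 2), 1)
    h <- sample(1:4, 1); w <- sample(1:6, 1)
    m[max(1, r - h):min(n, r + h), max(1, c - w):min(n, c + w)] <- TRUE
  }
  m
}
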