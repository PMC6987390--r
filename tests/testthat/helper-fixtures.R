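# Shared fixture builders.  All geometry fixtures are generated in code;
# segment matrices use the package's column convention
# (x1 y1 z1 x2 y2 z2 r1 r2).

seg_mat <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- c("x1", "y1", "z1", "x2", "y2", "z2", "r1", "r2")
  m
}

one_seg <- function(p, q, r = 0.3) seg_mat(c(p, q, r, r))

# n random segments of given length with isotropic orientation, midpoints
# uniform in the core of the box so the segment stays inside
random_segments_in_box <- function(n, len, box_dims, r = 0.3,
                                   direction = NULL) {
  out <- matrix(NA_real_, n, 8)
  for (i in seq_len(n)) {
    repeat {
      u <- if (is.null(direction)) {
        v <- rnorm(3); v / sqrt(sum(v^2))
      } else direction / sqrt(sum(direction^2))
      mid <- runif(3) * box_dims
      p <- mid - u * len / 2
      q <- mid + u * len / 2
      if (all(p >= 0) && all(p <= box_dims) && all(q >= 0) &&
          all(q <= box_dims)) break
    }
    out[i, ] <- c(p, q, r, r)
  }
  colnames(out) <- c("x1", "y1", "z1", "x2", "y2", "z2", "r1", "r2")
  out
}

unit_box <- function(dims) list(origin = c(0, 0, 0), dims = dims)

# independent exact segment-segment intersection oracle: solves the 2x2
# linear system p + t (q - p) = a + s (b - a) and counts interior hits
oracle_seg_cross <- function(p1, p2, q1, q2) {
  A <- cbind(p2 - p1, q1 - q2)
  if (abs(det(A)) < 1e-14) return(FALSE)
  ts <- solve(A, q1 - p1)
  ts[1] >= 0 && ts[1] < 1 && ts[2] >= 0 && ts[2] < 1
}
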