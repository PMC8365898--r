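# Independent oracles and small fixture builders used across the suite.

# random rotation matrix (uniform-ish via QR of Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# exhaustive support-corner scan: index maximizing u . p over all vertices
oracle_support_corner <- function(points, u) {
  which.max(points %*% u)
}

# exhaustive chord-to-vertex perpendicular distance scan (concave side =
# side holding the dominant deviation)
oracle_concave_depth <- function(arc) {
  a <- arc[1, ]; b <- arc[nrow(arc), ]
  L <- sqrt(sum((b - a)^2))
  if (L == 0) return(max(sqrt(rowSums(sweep(arc, 2, a)^2))))
  best_pos <- 0; best_neg <- 0
  for (i in seq_len(nrow(arc))) {
    p <- arc[i, ]
    s <- ((b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])) / L
    if (s > best_pos) best_pos <- s
    if (-s > best_neg) best_neg <- -s
  }
  max(best_pos, best_neg)
}

# exact Wilcoxon signed-rank two-sided p by explicit sign-pattern matrix
oracle_wilcoxon_exact <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  sums <- as.vector(signs %*% r)
  tol <- 1e-9
  min(1, 2 * min(mean(sums <= W + tol), mean(sums >= W - tol)))
}

# smooth random star-shaped closed CCW curve around the origin
random_star_curve <- function(n = 120, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- 1 + 0.25 * runif(1) * cos(2 * th + runif(1, 0, pi)) +
    0.15 * runif(1) * cos(3 * th + runif(1, 0, pi))
  structure(list(points = cbind(r * cos(th), r * sin(th)), label = "M"),
            class = "vm_planar_curve")
}

# total loop length of a closed section polyline
loop_length <- function(section) {
  p <- section$points
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_vertebra(vertebra_params())
    cache
  }
})
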