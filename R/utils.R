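#' @importFrom stats rnorm runif sd quantile approx median setNames
#' @importFrom methods new validObject is slot
NULL

# Derive a child seed from a master seed and a stage/index counter.
# Kept strictly below 2^31 so it is always a valid R integer seed.
deriveSeed <- function(seed, stage, index = 0L) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729 + index * 7907) %% 2147483647)
}

# Gaussian draw restricted to a window symmetric about `mean` so that
# truncation cannot bias the configured mean. The half-width is the smaller
# of `nsd` standard deviations and the distance to the nearest physical bound.
rnormBounded <- function(n, mean, sd, lower = -Inf, upper = Inf, nsd = 2.5) {
  if (sd <= 0) return(rep(mean, n))
  half <- min(nsd * sd, mean - lower, upper - mean)
  if (half <= 0) stop("mean lies outside the physical bounds [", lower, ", ", upper, "]")
  out <- numeric(n)
  todo <- seq_len(n)
  for (it in 1:1000) {
    draw <- rnorm(length(todo), mean, sd)
    ok <- abs(draw - mean) <= half
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
    if (!length(todo)) return(out)
  }
  out[todo] <- mean
  out
}

# Eigenvalues of many symmetric 3x3 matrices at once (trigonometric method).
# Input: matrices given componentwise as vectors. Returns a n x 3 matrix of
# eigenvalues sorted ascending per row.
symEigen3 <- function(a11, a22, a33, a12, a13, a23) {
  n <- length(a11)
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  ev <- matrix(q, n, 3)
  nz <- p > 1e-300
  if (any(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b13 <- a13[nz] / p[nz]; b23 <- a23[nz] / p[nz]
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q[nz] + 2 * p[nz] * cos(phi)
    e3 <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    e2 <- 3 * q[nz] - e1 - e3
    ev[nz, 1] <- e3; ev[nz, 2] <- e2; ev[nz, 3] <- e1
  }
  ev
}

# Eigenvalues of many symmetric 2x2 matrices. Returns n x 2, ascending.
symEigen2 <- function(a11, a22, a12) {
  m <- (a11 + a22) / 2
  d <- sqrt(pmax(((a11 - a22) / 2)^2 + a12^2, 0))
  cbind(m - d, m + d)
}

# Engineering strain (%) of a material fiber from a Green-Lagrange quadratic
# form value eta = d' E d: 100 * (sqrt(1 + 2 eta) - 1).
stretchStrain <- function(eta, context = "strain") {
  arg <- 1 + 2 * eta
  if (any(arg <= 0)) {
    stop("unphysical compression in ", context, ": 1 + 2*d'Ed <= 0")
  }
  100 * (sqrt(arg) - 1)
}

rowsNormalize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("cannot normalize a zero-length vector")
  m / nrm
}

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
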