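# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the ambient
# RNG stream is untouched. seed = NULL means "use the ambient stream" so that
# callers can run whole batches under one outer seed.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Intrinsic rotation matrix from three angles (radians), applied as
# lab = R %*% body with R = Rz(c) %*% Ry(b) %*% Rx(a).
rotation_matrix <- function(angles) {
  a <- angles[1]; b <- angles[2]; c <- angles[3]
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# n uniform points in the unit ball, as an n x 3 matrix.
runif_ball <- function(n) {
  x <- matrix(rnorm(3 * n), ncol = 3)
  len <- sqrt(rowSums(x^2))
  len[len == 0] <- 1
  r <- runif(n)^(1 / 3)
  x * (r / len)
}

as_point_matrix <- function(pts) {
  if (is.data.frame(pts)) pts <- as.matrix(pts[, c("x", "y", "z")])
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  storage.mode(pts) <- "double"
  pts
}

# Normalized 1-D Gaussian kernel (unit sum) with half-width 4 sigma.
gauss_kernel <- function(sigma_vox, half_width = 4) {
  r <- max(1L, ceiling(half_width * sigma_vox))
  t <- seq.int(-r, r)
  k <- exp(-t^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Discrete second derivative of the normalized Gaussian; zero-sum corrected
# so flat regions give exactly zero response.
gauss_deriv2_kernel <- function(sigma_vox, half_width = 4) {
  r <- max(2L, ceiling(half_width * sigma_vox))
  t <- seq.int(-r, r)
  g <- exp(-t^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  k <- g * (t^2 - sigma_vox^2) / sigma_vox^4
  k - mean(k)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
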