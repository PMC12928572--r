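#' Kernel hyperparameters for the warped GP
#'
#' @param amplitude Kernel variance a (warped-response units squared);
#'   controls how far the latent function can move from the zero prior mean.
#' @param length_scale Isotropic length scale l, in normalized coordinate
#'   units (see [normalize_coords()]).
#' @param noise_var Observation noise variance sigma_eps^2 in warped space.
#' @return An object of class `"kernel_params"`.
#' @export
kernel_params <- function(amplitude, length_scale, noise_var) {
  if (amplitude <= 0) stop("kernel amplitude must be > 0")
  if (length_scale <= 0) stop("kernel length scale must be > 0")
  if (noise_var < 0) stop("noise variance must be >= 0")
  structure(list(amplitude = amplitude, length_scale = length_scale,
                 noise_var = noise_var),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("RBF kernel: a = %.4g, l = %.4g (normalized), sigma_eps^2 = %.4g\n",
              x$amplitude, x$length_scale, x$noise_var))
  invisible(x)
}

# Squared Euclidean cross-distance matrix between row sets A and B.
sq_dist <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  D2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  pmax(D2, 0)
}

#' Squared-exponential (RBF) kernel matrix
#'
#' Entry (i, j) is a * exp(-||A_i - B_j||^2 / (2 l^2)). Inputs must already
#' be in normalized coordinates ([normalize_coords()]); the noise term is
#' not added here.
#'
#' @param A,B Numeric matrices of normalized coordinates, one row per point.
#' @param kernel A [kernel_params()] object.
#' @return The `nrow(A)` x `nrow(B)` covariance matrix.
#' @export
rbf_kernel_matrix <- function(A, B, kernel) {
  stopifnot(inherits(kernel, "kernel_params"))
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("A and B must have the same dimensionality")
  kernel$amplitude * exp(-sq_dist(A, B) / (2 * kernel$length_scale^2))
}

# Cholesky with jitter escalation. Returns list(L = upper-tri chol factor,
# jitter used). Errors after the ladder is exhausted.
chol_jitter <- function(M, ladder = c(0, 1e-10, 1e-8, 1e-6)) {
  n <- nrow(M)
  for (j in ladder) {
    L <- tryCatch(chol(M + diag(j, n)), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j))
  }
  stop(sprintf(paste0("covariance matrix not positive definite after jitter ",
                      "up to %g (n = %d, diag range [%.3g, %.3g])"),
               max(ladder), n, min(diag(M)), max(diag(M))))
}
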