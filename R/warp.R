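#' Square-root warping of MEP amplitudes
#'
#' MEP amplitudes are nonnegative, so the GP is fit on the warped response
#' z = sqrt(r); back-transformed predictions then respect nonnegativity.
#'
#' @param r Nonnegative response amplitude(s).
#' @return The warped value(s) z = sqrt(r).
#' @seealso [unwarp_mean_var()]
#' @export
warp_response <- function(r) {
  if (any(!is.finite(r))) stop("responses must be finite")
  bad <- which(r < 0)
  if (length(bad))
    stop(sprintf("negative response in trial(s) %s: warping requires r >= 0",
                 paste(utils::head(bad, 5), collapse = ", ")))
  sqrt(r)
}

#' Posterior mean response from warped-space moments
#'
#' If the warped response z is Gaussian with mean `mu_z` and variance
#' `var_z`, the expected unwarped response is E\[z^2\] = mu_z^2 + var_z
#' (exact, not a delta-method approximation).
#'
#' @param mu_z Posterior mean(s) in warped space.
#' @param var_z Posterior variance(s) in warped space, nonnegative.
#' @return Expected response amplitude(s), nonnegative.
#' @export
unwarp_mean_var <- function(mu_z, var_z) {
  if (any(var_z < 0)) stop("warped-space variance must be nonnegative")
  mu_z^2 + var_z
}
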