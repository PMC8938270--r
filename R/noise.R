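#' Biopsy genotyping noise profile
#'
#' Error decomposition for amplified few-cell embryo biopsy genotyping:
#' \describe{
#'   \item{ado}{allele dropout — probability that a truly heterozygous site is
#'     called as one of the two homozygotes (uniformly either one). Dropout of
#'     one allele of a homozygote is observationally silent and is folded into
#'     `error`.}
#'   \item{error}{random miscall probability, spread uniformly over the two
#'     wrong genotype calls.}
#'   \item{missing}{no-call probability, independent of the true genotype.}
#' }
#'
#' The `"day3"` (single-cell blastomere) and `"day5"` (multi-cell
#' trophectoderm) presets encode the expectation that single-cell biopsies
#' genotype less reliably; the preset rates are package calibration constants,
#' chosen as plausible for amplified single-/few-cell SNP-array data, and can
#' be overridden freely.
#'
#' @param ado allele-dropout rate in \[0, 1).
#' @param error random miscall rate in \[0, 1).
#' @param missing no-call rate in \[0, 1).
#' @param label free-text label.
#' @return An object of class `noise_profile`.
#' @examples
#' noise_profile("day5")
#' noise_profile(ado = 0.15, error = 0.01, missing = 0.05, label = "custom")
#' @export
noise_profile <- function(ado = 0, error = 0, missing = 0, label = "custom") {
  if (is.character(ado) && length(ado) == 1) {
    return(switch(ado,
      day3 = noise_profile(0.10, 0.01, 0.05, "day3"),
      day5 = noise_profile(0.02, 0.005, 0.02, "day5"),
      none = noise_profile(0, 0, 0, "none"),
      wgr_stop(sprintf("unknown noise preset '%s'", ado), "noise_profile")
    ))
  }
  rates <- c(ado = ado, error = error, missing = missing)
  if (any(rates < 0 | rates >= 1)) {
    wgr_stop("noise rates must lie in [0, 1)", "noise_profile")
  }
  structure(list(ado = ado, error = error, missing = missing, label = label),
            class = "noise_profile")
}

#' @export
print.noise_profile <- function(x, ...) {
  cat(sprintf("<noise_profile '%s'> ADO %.3f, miscall %.3f, no-call %.3f\n",
              x$label, x$ado, x$error, x$missing))
  invisible(x)
}

#' Genotype-call emission distribution under a noise profile
#'
#' Probability of each observed call (dosage 0/1/2) and of a no-call, given
#' the true dosage. This is exactly the generative model used by
#' [make_observation()], so the HMM emission term and the simulator agree.
#'
#' @param profile a [noise_profile()].
#' @return 3x4 matrix: rows = true dosage 0..2, columns = observed
#'   0, 1, 2, no-call. Rows sum to one.
#' @export
emission_matrix <- function(profile) {
  stopifnot(inherits(profile, "noise_profile"))
  ado <- profile$ado; e <- profile$error; m <- profile$missing
  # stage 1: allele dropout (hets only)
  drop <- diag(3)
  drop[2, ] <- c(ado / 2, 1 - ado, ado / 2)
  # stage 2: random miscall to either wrong genotype
  err <- matrix(e / 2, 3, 3); diag(err) <- 1 - e
  visible <- drop %*% err
  out <- cbind(visible * (1 - m), rep(m, 3))
  dimnames(out) <- list(true = 0:2, obs = c(0:2, "nocall"))
  out
}
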