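#' Deterministic digital validation phantom
#'
#' A small, fully deterministic test object used for cross-implementation
#' validation of the feature engine: an ellipsoidal mask (semi-axes
#' 16 x 12 x 10 mm) on a 20 x 18 x 14 grid with 2 x 2 x 2.4 mm spacing,
#' whose intensities combine a linear radial falloff with a fixed
#' trigonometric ripple (no randomness involved), giving a wide spread of
#' gray levels and nontrivial texture in every matrix class.
#'
#' The same closed-form definition is implemented in the independent
#' reference-oracle script (`tools/reference_features_oracle.py`) whose
#' frozen output ships in `inst/extdata/`.
#'
#' @return List with `image` (a [pet_volume()]) and `mask` (a [voi_mask()]).
#' @export
digital_phantom <- function() {
  d <- c(20L, 18L, 14L)
  sp <- c(2.0, 2.0, 2.4)
  ctr <- (d + 1) / 2
  i <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  j <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  k <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  ux <- (i - ctr[1]) * sp[1]
  uy <- (j - ctr[2]) * sp[2]
  uz <- (k - ctr[3]) * sp[3]
  r <- sqrt((ux / 16)^2 + (uy / 12)^2 + (uz / 10)^2)
  mask <- r <= 1
  val <- 1.0 + 1.6 * pmax(0, 1 - r) +
    0.30 * sin(1.7 * i) * cos(2.3 * j) * sin(1.1 * k) +
    0.15 * cos(0.7 * i + 1.3 * j + 2.1 * k)
  list(image = pet_volume(val, sp, "digital"),
       mask = voi_mask(mask, "phantom", NA_real_, sp))
}
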