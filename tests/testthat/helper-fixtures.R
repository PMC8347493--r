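# Small constructed fixtures used across test files.

# fundus image from explicit red/green matrices (blue = 0 unless given)
px_image <- function(red, green, blue = NULL, ...) {
  red <- as.matrix(red); green <- as.matrix(green)
  blue <- if (is.null(blue)) matrix(0, nrow(red), ncol(red)) else as.matrix(blue)
  fundus_image(red, green, blue, ...)
}

# masks where the whole frame is disc and `vessel_idx` (linear indices) are vessels
full_disc_masks <- function(dim, vessel_idx = integer()) {
  disc <- matrix(TRUE, dim[1], dim[2])
  vess <- matrix(FALSE, dim[1], dim[2])
  vess[vessel_idx] <- TRUE
  disc_masks(disc, vess)
}

# a filled circle mask
circle_mask <- function(n, cy, cx, r) {
  d <- sqrt((row(matrix(0, n, n)) - cy)^2 + (col(matrix(0, n, n)) - cx)^2)
  d <= r
}

# visual field over the 16 default TCV positions with given thresholds
tcv_field <- function(thresholds) {
  pos <- tcv_positions()
  visual_field(data.frame(x = pos$x, y = pos$y, threshold = thresholds))
}

# brute-force Mann-Whitney AUC oracle: all case/control pairs, ties = 1/2
auc_oracle <- function(scores, labels, positive = "glaucoma") {
  x <- scores[labels == positive]
  y <- scores[labels != positive]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}
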