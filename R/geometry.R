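#' Minimum-image displacement under an orthorhombic periodic box
#'
#' Displacement from `a` to `b` wrapped into the nearest periodic image.
#' Inputs may be length-3 vectors or n x 3 matrices (row-wise points).
#'
#' @param a,b Cartesian coordinates in Angstrom (length-3 vector or n x 3
#'   matrix).
#' @param box Length-3 vector of orthorhombic box edges in Angstrom.
#' @return Displacement `b - a` mapped into `[-box/2, box/2)` per component,
#'   same shape as the inputs.
#' @export
min_image_disp <- function(a, b, box) {
  box <- check_box(box)
  d <- b - a
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  } else {
    d <- d - box * round(d / box)
  }
  d
}

#' Minimum-image distance
#'
#' Euclidean distance between points under the minimum-image convention for
#' an orthorhombic box: the smallest distance over all periodic images. It
#' is bounded above by the non-periodic distance and by half the box
#' diagonal.
#'
#' @inheritParams min_image_disp
#' @return Distance in Angstrom (scalar, or length-n vector for matrix
#'   input).
#' @export
minimum_image_distance <- function(a, b, box) {
  d <- min_image_disp(a, b, box)
  if (is.matrix(d)) sqrt(rowSums(d * d)) else sqrt(sum(d * d))
}

#' All-pairs minimum-image distance matrix
#'
#' @param A n x 3 coordinate matrix (Angstrom).
#' @param B m x 3 coordinate matrix (Angstrom).
#' @param box Length-3 orthorhombic box edges (Angstrom).
#' @return n x m matrix of minimum-image distances.
#' @export
pairwise_min_image <- function(A, B, box) {
  box <- check_box(box)
  A <- as_coord_matrix(A)
  B <- as_coord_matrix(B)
  acc <- 0
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    acc <- acc + dk * dk
  }
  sqrt(acc)
}

#' Minimum distance between two atom sets
#'
#' @inheritParams pairwise_min_image
#' @return Scalar minimum over all cross pairs (Angstrom).
#' @export
set_min_distance <- function(A, B, box) {
  min(pairwise_min_image(A, B, box))
}

#' Wrap coordinates into the primary box [0, box)
#'
#' @param x n x 3 matrix or length-3 vector (Angstrom).
#' @param box Length-3 box edges.
#' @return Wrapped coordinates, same shape.
#' @export
wrap_coords <- function(x, box) {
  box <- check_box(box)
  if (is.matrix(x)) {
    for (k in 1:3) x[, k] <- x[, k] - box[k] * floor(x[, k] / box[k])
  } else {
    x <- x - box * floor(x / box)
  }
  x
}

check_box <- function(box) {
  box <- as.numeric(box)
  if (length(box) == 9) {
    m <- matrix(box, 3, 3)
    if (any(abs(m[lower.tri(m) | upper.tri(m)]) > 1e-9))
      stop("triclinic boxes are not supported; supply an orthorhombic box ",
           "(3 edge lengths)")
    box <- diag(m)
  }
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be 3 positive orthorhombic edge lengths (Angstrom)")
  box
}

as_coord_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3) stop("coordinate matrix must have 3 columns")
    return(x)
  }
  matrix(as.numeric(x), ncol = 3, byrow = TRUE)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

normalize3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}
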