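#' Fit a helix axis by principal component analysis
#'
#' The axis is the dominant principal direction of the CA coordinates in the
#' given range, with its sign fixed to point in the N-to-C direction (the
#' dot product with \code{CA_last - CA_first} is positive).  The centroid is
#' the mean CA position.
#'
#' @param s a \linkS4class{BackboneStructure}.
#' @param range residue range \code{c(start, end)}, at least 5 residues.
#' @param index helix index to record (1..7; 0 when unknown).
#' @return a \linkS4class{HelixSegment}.
#' @export
fitHelixAxis <- function(s, range, index = 0L) {
  range <- as.integer(range)
  if (range[2] - range[1] + 1L < 5L) stop("degenerate helix: range too short")
  ca <- caCoords(s, range[1]:range[2])
  centroid <- colMeans(ca)
  sv <- svd(sweep(ca, 2, centroid))
  axis <- sv$v[, 1]
  nc <- ca[nrow(ca), ] - ca[1, ]
  if (sum(axis * nc) < 0) axis <- -axis
  new("HelixSegment", index = as.integer(index), range = range,
      axis = axis / vnorm(axis), centroid = centroid)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between a
#' mobile point set and a reference point set of equal size.
#'
#' @param mobile m-by-3 matrix of mobile points.
#' @param reference m-by-3 matrix of reference points.
#' @return a \linkS4class{SuperpositionResult}; a mobile point \code{x} maps
#'   to \code{rotation \%*\% x + translation}.
#' @export
kabschSuperpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) stop("point sets must have equal length")
  if (nrow(mobile) < 3L) stop("need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm); R0 <- sweep(reference, 2, cr)
  if (min(svd(M)$d[1:2]) < 1e-9 || min(svd(R0)$d[1:2]) < 1e-9)
    stop("points are collinear; superposition is not unique")
  H <- t(M) %*% R0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- M %*% t(Rm)
  rmsd <- sqrt(mean(rowSums((fitted - R0)^2)))
  new("SuperpositionResult", rotation = Rm,
      translation = as.numeric(cr - Rm %*% cm), rmsd = rmsd)
}

#' Region-restricted CA RMSD between a model and a native structure
#'
#' CA-only RMSD after optimal superposition restricted to the residues of a
#' region: \code{"TM"} (union of the seven helix ranges), \code{"FL"} (all
#' residues), or \code{"loops"} (union of the loop ranges).
#'
#' @param model,native equal-length \linkS4class{BackboneStructure} objects
#'   sharing the topology.
#' @param region one of \code{"TM"}, \code{"FL"}, \code{"loops"}.
#' @param topology the shared \linkS4class{Topology}.
#' @return RMSD in angstroms.
#' @export
regionRMSD <- function(model, native, region = c("TM", "FL", "loops"),
                       topology) {
  region <- match.arg(region)
  if (nResidues(model) != nResidues(native))
    stop("model and native differ in length")
  if (topology@n != nResidues(model))
    stop("topology does not match the structures")
  idx <- regionResidues(topology, region)
  if (length(idx) == 0L) stop("region contains no residues")
  kabschSuperpose(caCoords(model, idx), caCoords(native, idx))@rmsd
}

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd = %.4f A\n", object@rmsd))
})

setMethod("show", "HelixSegment", function(object) {
  cat(sprintf("HelixSegment %d [%d-%d]: axis (%.3f, %.3f, %.3f)\n",
              object@index, object@range[1], object@range[2],
              object@axis[1], object@axis[2], object@axis[3]))
})
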