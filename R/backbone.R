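.BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct a backbone structure
#'
#' @param coords numeric matrix, \code{4 * n} rows (N, CA, C, O per residue)
#'   and 3 columns.
#' @param chain single-character chain id.
#' @param originalIds optional original residue numbering (defaults to
#'   \code{1:n}).
#' @return a \linkS4class{BackboneStructure}.
#' @export
BackboneStructure <- function(coords, chain = "A", originalIds = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) %% 4L != 0L)
    stop("coords must contain 4 backbone atoms per residue")
  n <- nrow(coords) %/% 4L
  if (n < 1L) stop("no residues")
  if (is.null(originalIds)) originalIds <- seq_len(n)
  new("BackboneStructure", coords = unname(coords), nres = as.integer(n),
      chain = as.character(chain), originalIds = as.integer(originalIds))
}

#' @describeIn BackboneStructure number of residues
#' @param x a \code{BackboneStructure}.
#' @export
nResidues <- function(x) x@nres

#' Atom coordinates of selected residues
#'
#' @param x a \linkS4class{BackboneStructure}.
#' @param residues residue indices (1-based, normalized numbering); default
#'   all.
#' @param atoms subset of \code{c("N", "CA", "C", "O")}.
#' @return coordinate matrix, rows in residue-major, atom-minor order.
#' @export
atomCoords <- function(x, residues = seq_len(nResidues(x)),
                       atoms = .BACKBONE_ATOMS) {
  ai <- match(atoms, .BACKBONE_ATOMS)
  if (anyNA(ai)) stop("unknown backbone atom name")
  rows <- as.vector(t(outer((residues - 1L) * 4L, ai, `+`)))
  x@coords[rows, , drop = FALSE]
}

#' CA coordinates
#'
#' @param x a \linkS4class{BackboneStructure}.
#' @param residues residue indices; default all.
#' @return n-by-3 matrix of CA positions.
#' @export
caCoords <- function(x, residues = seq_len(nResidues(x))) {
  x@coords[(residues - 1L) * 4L + 2L, , drop = FALSE]
}

# Row indices into the coordinate matrix of all atoms of `residues`.
atomRows <- function(residues) {
  as.vector(t(outer((residues - 1L) * 4L, 1:4, `+`)))
}

# Replace all atom coordinates of `residues` with `value` (rigid graft).
`residueCoords<-` <- function(x, residues, value) {
  x@coords[atomRows(residues), ] <- value
  x
}

setMethod("show", "BackboneStructure", function(object) {
  cat("BackboneStructure: ", object@nres, " residues, chain ",
      object@chain, "\n", sep = "")
  cat("  original numbering ", object@originalIds[1], "..",
      object@originalIds[object@nres], "\n", sep = "")
})

#' Read a backbone structure from a PDB file
#'
#' Keeps the four backbone atoms N, CA, C, O of every residue of one chain.
#' Residues missing any backbone atom are rejected, as are insertion codes;
#' of alternate locations the first is kept.  Residue numbering is
#' normalized to 1..n (original ids retained for output).
#'
#' @param path path to a PDB file containing ATOM records.
#' @param chain chain identifier to read (default \code{"A"}).
#' @return a \linkS4class{BackboneStructure}.
#' @export
readPDBBackbone <- function(path, chain = "A") {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain not found: ", chain)
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported")
  at <- at[at$elety %in% .BACKBONE_ATOMS, , drop = FALSE]
  # first altloc only
  key <- paste(at$resno, at$elety)
  at <- at[!duplicated(key), , drop = FALSE]
  resno <- sort(unique(at$resno))
  n <- length(resno)
  coords <- matrix(NA_real_, 4L * n, 3L)
  for (i in seq_len(n)) {
    sub <- at[at$resno == resno[i], , drop = FALSE]
    m <- match(.BACKBONE_ATOMS, sub$elety)
    if (anyNA(m))
      stop("incomplete residue ", resno[i], ": missing ",
           paste(.BACKBONE_ATOMS[is.na(m)], collapse = ", "))
    coords[(i - 1L) * 4L + 1:4, ] <-
      as.matrix(sub[m, c("x", "y", "z")])
  }
  BackboneStructure(coords, chain = chain, originalIds = resno)
}

#' Write a backbone structure to a PDB file
#'
#' Emits standard ATOM records (coordinates to 3 decimals) with atoms
#' ordered N, CA, C, O within each residue, using the structure's original
#' residue numbering.
#'
#' @param s a \linkS4class{BackboneStructure}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writePDBBackbone <- function(s, path) {
  stopifnot(is(s, "BackboneStructure"))
  n <- nResidues(s)
  if (n < 1L) stop("no residues")
  elety <- rep(.BACKBONE_ATOMS, n)
  resno <- rep(s@originalIds, each = 4L)
  bio3d::write.pdb(file = path, xyz = as.vector(t(s@coords)),
                   type = rep("ATOM", 4L * n), eleno = seq_len(4L * n),
                   elety = elety, resid = rep("ALA", 4L * n),
                   chain = rep(s@chain, 4L * n), resno = resno)
  invisible(path)
}

#' Construct a 7-TM topology
#'
#' Loop ranges may be given explicitly or derived as the complement of the
#' TM ranges within \code{1..n}.
#'
#' @param tmRanges 7x2 matrix (or list of 7 \code{c(start, end)} pairs) of
#'   1-based inclusive TM helix ranges, in chain order.
#' @param n chain length.
#' @param loopRanges optional explicit loop ranges; derived when \code{NULL}.
#' @return a \linkS4class{Topology}.
#' @export
Topology <- function(tmRanges, n, loopRanges = NULL) {
  if (is.list(tmRanges)) tmRanges <- do.call(rbind, tmRanges)
  tmRanges <- matrix(as.integer(tmRanges), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  n <- as.integer(n)
  if (is.null(loopRanges)) {
    inTM <- rep(FALSE, n)
    for (i in seq_len(nrow(tmRanges))) inTM[tmRanges[i, 1]:tmRanges[i, 2]] <- TRUE
    r <- rle(inTM)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- !r$values
    loopRanges <- cbind(start = starts[keep], end = ends[keep])
  } else {
    if (is.list(loopRanges)) loopRanges <- do.call(rbind, loopRanges)
    loopRanges <- matrix(as.integer(loopRanges), ncol = 2L,
                         dimnames = list(NULL, c("start", "end")))
  }
  new("Topology", tmRanges = tmRanges, loopRanges = loopRanges, n = n)
}

#' @describeIn Topology TM helix ranges (7x2 matrix)
#' @param x a \code{Topology}.
#' @export
tmRanges <- function(x) x@tmRanges

#' @describeIn Topology loop ranges (k x 2 matrix)
#' @export
loopRanges <- function(x) x@loopRanges

# Residue indices of a region: "TM" (union of helix ranges), "FL" (all),
# "loops" (union of loop ranges).
regionResidues <- function(topology, region = c("TM", "FL", "loops")) {
  region <- match.arg(region)
  rangesToIdx <- function(m)
    if (nrow(m) == 0L) integer(0) else
      unlist(lapply(seq_len(nrow(m)), function(i) m[i, 1]:m[i, 2]))
  switch(region,
         FL = seq_len(topology@n),
         TM = sort(rangesToIdx(topology@tmRanges)),
         loops = sort(rangesToIdx(topology@loopRanges)))
}

setMethod("show", "Topology", function(object) {
  cat("Topology: n =", object@n, "\n")
  cat("  TM: ", paste(sprintf("%d-%d", object@tmRanges[, 1],
                              object@tmRanges[, 2]), collapse = " "), "\n")
  if (nrow(object@loopRanges))
    cat("  loops:", paste(sprintf("%d-%d", object@loopRanges[, 1],
                                  object@loopRanges[, 2]), collapse = " "), "\n")
})

#' Read a topology from a YAML file
#'
#' The file must contain \code{n} and \code{tm} (a list of 7
#' \code{[start, end]} pairs); \code{loops} is optional and derived from the
#' complement when absent.
#'
#' @param path YAML file path.
#' @return a \linkS4class{Topology}.
#' @export
readTopology <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$tm) || is.null(y$n)) stop("topology file must define 'n' and 'tm'")
  Topology(lapply(y$tm, as.integer), n = y$n,
           loopRanges = if (is.null(y$loops)) NULL else lapply(y$loops, as.integer))
}

#' Write a topology to a YAML file
#'
#' @param topology a \linkS4class{Topology}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeTopology <- function(topology, path) {
  y <- list(n = topology@n,
            tm = lapply(seq_len(7), function(i) as.integer(topology@tmRanges[i, ])),
            loops = lapply(seq_len(nrow(topology@loopRanges)),
                           function(i) as.integer(topology@loopRanges[i, ])))
  yaml::write_yaml(y, path)
  invisible(path)
}
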