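## Chaos game representation on a 12-sided regular polygon.
##
## Vertex k sits at (cos((k-1)*pi/6), sin((k-1)*pi/6)), so V1 = (1, 0)
## and all vertices lie on the unit circle.  Starting from the center
## P0 = (0, 0), each residue selects the vertex of its group and the next
## trajectory point is the midpoint of the previous point and that
## vertex.  Every trajectory point is a strict convex combination of an
## interior point and a unit-circle vertex, hence has norm < 1.
##
## The disc is divided into 24 equal angular sectors of width pi/12;
## sector k covers polar angles [(k-1)*pi/12, k*pi/12), counted
## counter-clockwise from the positive x-axis.  A point exactly on a
## boundary ray is assigned to the lower-index adjacent sector (angle 0
## belongs to sector 1).

#' Vertex coordinates of the 12-sided chaos-game polygon
#'
#' @return A 12 x 2 matrix; row k is
#'   `(cos((k-1)*pi/6), sin((k-1)*pi/6))`, so row 1 is `(1, 0)` and all
#'   rows have unit norm.
#' @export
cgrVertices <- function() {
  k <- 1:12
  m <- cbind(x = cos((k - 1) * pi / 6), y = sin((k - 1) * pi / 6))
  rownames(m) <- sprintf("V%d", k)
  m
}

#' Chaos-game trajectory of a sequence
#'
#' Iterates the midpoint map: point `i` is the midpoint of point `i - 1`
#' (point 0 being the polygon center) and the vertex assigned to residue
#' `i` by the 12-group alphabet.
#'
#' @param x A single validated sequence (character scalar or
#'   `AAString`-like).
#' @param alphabet A 12-group [AminoAlphabet-class]; group k maps to
#'   vertex k.
#' @return An `L x 2` numeric matrix of trajectory points.
#' @examples
#' cgrTrajectory("AA")  # (0.5, 0) then (0.75, 0): A sits on vertex 1
#' @export
cgrTrajectory <- function(x, alphabet = cgrAlphabet()) {
  if (nGroups(alphabet) != 12L)
    stop("CGR requires a 12-group alphabet; '", alphabet@name, "' has ",
         nGroups(alphabet))
  s <- toupper(as.character(x))
  stopifnot(length(s) == 1L)
  if (!nzchar(s)) stop("cannot draw a trajectory for an empty sequence")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  lut <- classOf(alphabet)
  v <- unname(lut[chars])
  if (anyNA(v)) {
    at <- which(is.na(v))[1L]
    stop("residue '", chars[at], "' at position ", at,
         " is not mapped by alphabet '", alphabet@name, "'")
  }
  verts <- cgrVertices()
  # x_i = x_{i-1}/2 + Vx_i/2 is a linear recursive filter.
  px <- as.numeric(stats::filter(verts[v, 1L] / 2, 0.5, "recursive"))
  py <- as.numeric(stats::filter(verts[v, 2L] / 2, 0.5, "recursive"))
  cbind(x = px, y = py)
}

#' Assign trajectory points to the 24 angular segments
#'
#' Sector k covers polar angles `[(k-1)*pi/12, k*pi/12)`; points exactly
#' on a boundary ray go to the lower-index adjacent sector, with angle 0
#' owned by sector 1.
#'
#' @param points An `N x 2` matrix of planar points (not at the origin).
#' @return Integer vector of segment indices in `1..24`.
#' @export
cgrSegments <- function(points) {
  points <- rbind(points)
  theta <- atan2(points[, 2L], points[, 1L])
  theta[theta < 0] <- theta[theta < 0] + 2 * pi
  w <- pi / 12
  m <- theta / w
  onBoundary <- abs(m - round(m)) < 1e-12
  idx <- floor(m) + 1L
  idx[onBoundary] <- pmax(round(m[onBoundary]), 1)
  idx[idx > 24L] <- 24L  # guard against theta ~ 2*pi round-off
  as.integer(idx)
}

#' Chaos game representation features (CGR, 24-d)
#'
#' `D_k = L_k / N`, where `L_k` is the number of the `N` trajectory
#' points falling in segment k.  Each row sums to 1.
#'
#' @param x An [Biostrings::AAStringSet] or (named) character vector of
#'   validated sequences, each of length at least 1.
#' @param alphabet A 12-group [AminoAlphabet-class].
#' @return A [ProteinFeatures-class] with 24 columns `S1..S24`.
#' @export
computeCGR <- function(x, alphabet = cgrAlphabet()) {
  seqs <- .asCharSeqs(x)
  if (any(!nzchar(seqs)))
    stop("empty sequence(s): ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  m <- t(vapply(seqs, function(s) {
    pts <- cgrTrajectory(s, alphabet)
    tabulate(cgrSegments(pts), 24L) / nrow(pts)
  }, numeric(24L)))
  dimnames(m) <- list(names(seqs), sprintf("S%d", 1:24))
  new("ProteinFeatures", values = m, featureSet = "CGR")
}

#' Plot a chaos-game trajectory
#'
#' Visual aid: draws the 12-gon, its unit-circle vertices, the 24
#' segment boundary rays and the trajectory points of one sequence.
#'
#' @param x A single validated sequence.
#' @param alphabet A 12-group [AminoAlphabet-class].
#' @param ... Further arguments passed to [graphics::points()].
#' @return Invisibly, the trajectory matrix.
#' @export
plotCGR <- function(x, alphabet = cgrAlphabet(), ...) {
  pts <- cgrTrajectory(x, alphabet)
  verts <- cgrVertices()
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 xlab = "", ylab = "", axes = FALSE)
  graphics::polygon(verts[, 1L], verts[, 2L], border = "grey40")
  for (k in 1:24) {
    a <- (k - 1) * pi / 12
    graphics::segments(0, 0, 1.05 * cos(a), 1.05 * sin(a),
                       col = "grey80", lty = 3)
  }
  graphics::text(1.09 * verts[, 1L], 1.09 * verts[, 2L],
                 groupLabels(alphabet), cex = 0.7)
  graphics::points(pts, pch = 20, cex = 0.4, ...)
  invisible(pts)
}
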