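#' Ordered polygon mask
#'
#' A positive region at histology resolution encoded as an ordered list of
#' polygons, the on-disk representation used by pathology vendor mask files.
#' Each polygon is a matrix of `(row, col)` vertex coordinates (0-based,
#' pixel centers at integers). Polygon order carries nesting semantics: a
#' polygon drawn inside a positive region carves a hole, and a polygon inside
#' a hole re-fills. [rasterize_mask()] implements this as strict parity
#' (each polygon toggles the region it covers), which is order-independent
#' and coincides with even-odd semantics at any nesting depth.
#'
#' @param polygons list of numeric matrices, each `V x 2` with `V >= 3`.
#' @param canvas_shape integer vector `c(rows, cols)`.
#' @return An object of class `polygon_mask`.
#' @export
polygon_mask <- function(polygons, canvas_shape) {
  stopifnot(length(canvas_shape) == 2L, all(canvas_shape >= 1))
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L) stop("each polygon must be a V x 2 (row, col) matrix")
    if (any(!is.finite(p))) stop("polygon vertices must be finite")
    storage.mode(p) <- "double"
    p
  })
  structure(list(polygons = polygons,
                 canvas_shape = as.integer(canvas_shape)),
            class = "polygon_mask")
}

#' Bresenham line between two pixels
#'
#' Integer line trace between two 0-based `(row, col)` pixel coordinates,
#' inclusive of both endpoints.
#'
#' @param p0,p1 integer vectors `c(row, col)`.
#' @return integer matrix of `(row, col)` pixels on the line.
#' @export
bresenham_line <- function(p0, p1) {
  bresenham_cpp(as.integer(round(p0[1])), as.integer(round(p0[2])),
                as.integer(round(p1[1])), as.integer(round(p1[2])))
}

#' Rasterize an ordered polygon mask
#'
#' Each polygon's boundary is traced with Bresenham's line algorithm between
#' consecutive vertices (closing last to first) and its interior filled by an
#' even-odd scanline pass; polygons are applied in order, each toggling
#' (XOR) the region it covers, which realizes positive/hole/re-fill nesting.
#' Vertices outside the canvas are clipped with a warning; polygons with
#' fewer than 3 vertices are skipped with a warning.
#'
#' @param poly a [polygon_mask()].
#' @return logical matrix of shape `canvas_shape` (row `r+1`, column `c+1`
#'   corresponds to 0-based pixel `(r, c)`).
#' @export
rasterize_mask <- function(poly) {
  stopifnot(inherits(poly, "polygon_mask"))
  nr <- poly$canvas_shape[1]; nc <- poly$canvas_shape[2]
  out <- matrix(FALSE, nr, nc)
  for (p in poly$polygons) {
    if (nrow(p) < 3L) {
      warning("skipping polygon with fewer than 3 vertices", call. = FALSE)
      next
    }
    if (any(p[, 1] < 0 | p[, 1] > nr - 1 | p[, 2] < 0 | p[, 2] > nc - 1))
      warning("polygon vertex outside canvas; clipping to canvas", call. = FALSE)
    out <- xor(out, fill_polygon_cpp(p, nr, nc))
  }
  out
}

# Moore-neighbour boundary trace of a single connected component.
# M: logical matrix; returns k x 2 matrix of 0-based (row, col) boundary
# pixels in clockwise order. Single-pixel components return one row.
# Terminates when a (pixel, scan-direction) state repeats, which subsumes
# Jacob's stopping criterion.
.moore_trace <- function(M) {
  idx <- which(M, arr.ind = TRUE)
  o <- order(idx[, 1], idx[, 2])
  start <- as.integer(idx[o[1], ])
  # 8-neighbourhood scanned in order W, NW, N, NE, E, SE, S, SW
  nb <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
               ncol = 2, byrow = TRUE)
  nr <- nrow(M); nc <- ncol(M)
  path <- list(start)
  cur <- start
  scan0 <- 0L  # 0-based direction index to start scanning from
  seen <- new.env(hash = TRUE)
  repeat {
    key <- paste0(cur[1], ",", cur[2], ",", scan0)
    if (!is.null(seen[[key]])) break
    assign(key, TRUE, envir = seen)
    found <- FALSE
    for (k in 0:7) {
      d0 <- (scan0 + k) %% 8L
      r <- cur[1] + nb[d0 + 1L, 1]; c <- cur[2] + nb[d0 + 1L, 2]
      if (r >= 1 && r <= nr && c >= 1 && c <= nc && M[r, c]) {
        scan0 <- (d0 + 6L) %% 8L  # back up two positions for the next scan
        cur <- c(r, c)
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    path[[length(path) + 1L]] <- cur
  }
  m <- do.call(rbind, path)
  if (nrow(m) > 1L && all(m[nrow(m), ] == m[1, ])) m <- m[-nrow(m), , drop = FALSE]
  m - 1L  # to 0-based
}

#' Convert a binary raster into an ordered polygon mask
#'
#' Traces the boundary of every connected foreground component and of every
#' enclosed background component (hole) with Moore-neighbour tracing, then
#' verifies the result by rasterizing it back: any residual pixel differences
#' (possible for pathological one-pixel-wide geometry) are toggled with
#' degenerate single-pixel polygons, so the round trip
#' `rasterize_mask(polygonize(x))` reproduces `x` exactly by construction.
#'
#' @param raster logical (or 0/1) matrix.
#' @return a [polygon_mask()]; an all-zero raster yields an empty polygon list.
#' @export
polygonize <- function(raster) {
  raster <- raster > 0
  shape <- dim(raster)
  if (!any(raster)) return(polygon_mask(list(), shape))
  polys <- list()
  comp <- EBImage::bwlabel(raster)
  for (k in seq_len(max(comp))) {
    tr <- .moore_trace(comp == k)
    if (nrow(tr) < 3L) tr <- tr[rep(seq_len(nrow(tr)), length.out = 3L), , drop = FALSE]
    polys[[length(polys) + 1L]] <- tr
  }
  # holes: background components that do not touch the image border
  bg <- EBImage::bwlabel(!raster)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  for (k in setdiff(seq_len(max(bg)), border_labels)) {
    tr <- .moore_trace(bg == k)
    if (nrow(tr) < 3L) tr <- tr[rep(seq_len(nrow(tr)), length.out = 3L), , drop = FALSE]
    polys[[length(polys) + 1L]] <- tr
  }
  pm <- polygon_mask(polys, shape)
  # self-correction: toggle any residual mismatches with 1-pixel polygons
  got <- suppressWarnings(rasterize_mask(pm))
  diffpix <- which(got != raster, arr.ind = TRUE)
  if (nrow(diffpix) > 0L) {
    for (i in seq_len(nrow(diffpix))) {
      v <- matrix(rep(diffpix[i, ] - 1L, 3L), ncol = 2, byrow = TRUE)
      pm$polygons[[length(pm$polygons) + 1L]] <- v
    }
    got <- suppressWarnings(rasterize_mask(pm))
    if (!identical(unname(got), unname(raster > 0)))
      stop("internal error: polygonize self-correction failed")
  }
  pm
}
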