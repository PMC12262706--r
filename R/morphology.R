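# Object circularity on binary/labeled segmentation masks.
#
# Circularity = 4 pi Area / Perimeter^2, with the area as the pixel count
# and the perimeter as the polygonal length of the marching-squares contour
# at level 0.5 (raw pixel-edge counting overestimates the perimeter and
# systematically deflates circularity; the polygonal estimator is recorded
# in the output metadata).

#' Label connected components of a binary mask
#'
#' 4-connectivity flood fill. Matrices that already contain labels (> 1
#' distinct positive values) are returned unchanged.
#'
#' @param mask integer/logical matrix; 0 (or FALSE) = background.
#' @return integer matrix of labels (0 background).
#' @export
label_mask <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  vals <- unique(as.vector(mask[mask != 0]))
  if (length(vals) > 1L) return(matrix(as.integer(mask), nrow(mask)))
  out <- matrix(0L, nrow(m), ncol(m))
  lab <- 0L
  nr <- nrow(m); nc <- ncol(m)
  for (start in which(m == 1L & out == 0L)) {
    if (out[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    out[start] <- lab
    while (length(queue)) {
      cur <- queue
      queue <- integer()
      r <- (cur - 1L) %% nr + 1L
      cl <- (cur - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1L]; cc <- cl + d[2L]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        idx <- (cc[ok] - 1L) * nr + rr[ok]
        idx <- idx[m[idx] == 1L & out[idx] == 0L]
        if (length(idx)) {
          out[idx] <- lab
          queue <- c(queue, idx)
        }
      }
      queue <- unique(queue)
    }
  }
  out
}

# Polygonal perimeter of one object via marching-squares contour at 0.5.
# The mask is zero-padded so objects touching the border still yield closed
# contours; with holes present the outer (longest) contour is used.
object_perimeter <- function(bin) {
  pad <- matrix(0, nrow(bin) + 2L, ncol(bin) + 2L)
  pad[2:(nrow(bin) + 1L), 2:(ncol(bin) + 1L)] <- bin
  cl <- grDevices::contourLines(x = seq_len(nrow(pad)), y = seq_len(ncol(pad)),
                                z = pad, levels = 0.5)
  if (length(cl) == 0L) return(NA_real_)
  per <- vapply(cl, function(cc) {
    xs <- c(cc$x, cc$x[1L]); ys <- c(cc$y, cc$y[1L])
    sum(sqrt(diff(xs)^2 + diff(ys)^2))
  }, numeric(1))
  max(per)
}

#' Per-object circularity of a mask
#'
#' @param mask binary or labeled integer matrix (0 = background). Binary
#'   masks are labeled with 4-connectivity first.
#' @param min_area minimum object area in pixels; smaller objects are
#'   dropped before measuring.
#' @param pixel_size optional pixel size (um/px), recorded in the output.
#' @return data frame with one row per object: \code{label},
#'   \code{area_px}, \code{perimeter_px}, \code{circularity},
#'   \code{clipped} (TRUE when the raw value exceeded 1 and was clipped,
#'   which slight discretization can cause). The perimeter estimator name is
#'   attached as attribute \code{perimeter_estimator}.
#' @examples
#' disc <- outer(1:41, 1:41, function(i, j) (i - 21)^2 + (j - 21)^2 <= 15^2)
#' circularity(disc)
#' @export
circularity <- function(mask, min_area = 5L, pixel_size = NULL) {
  if (!is.matrix(mask)) stop_domain("mask must be a matrix")
  lab <- label_mask(mask)
  labels <- sort(unique(as.vector(lab[lab > 0L])))
  if (length(labels) == 0L) stop_domain("mask contains no objects")
  rows <- lapply(labels, function(L) {
    bin <- matrix(as.integer(lab == L), nrow(lab))
    area <- sum(bin)
    if (area < min_area) return(NULL)
    per <- object_perimeter(bin)
    raw <- 4 * pi * area / per^2
    data.frame(label = L, area_px = area, perimeter_px = per,
               circularity = min(raw, 1), clipped = raw > 1)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) stop_domain("no objects pass the min_area filter")
  out <- do.call(rbind, rows)
  attr(out, "perimeter_estimator") <- "marching-squares polygonal contour"
  attr(out, "pixel_size_um") <- pixel_size
  out
}

#' Read a mask from a plain-text image file
#'
#' Supports ASCII PGM (P2) and P1 bitmaps, and CSV matrices. (Plain-text
#' stand-ins for the 16-bit TIFF/PNG label images produced upstream.)
#'
#' @param path file path (.pgm or .csv).
#' @return integer matrix.
#' @export
read_mask <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    return(as.matrix(utils::read.csv(path, header = FALSE)))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  magic <- trimws(lines[1L])
  if (!magic %in% c("P1", "P2"))
    stop_domain("unsupported mask format (expect ASCII PGM P1/P2 or CSV)")
  vals <- as.integer(unlist(strsplit(paste(lines[-1L], collapse = " "),
                                     "\\s+")))
  vals <- vals[!is.na(vals)]
  w <- vals[1L]; h <- vals[2L]
  px <- if (magic == "P2") vals[-(1:3)] else vals[-(1:2)]
  if (length(px) != w * h) stop_domain("mask pixel count does not match header")
  # PGM is row-major top-to-bottom; store as h x w matrix
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}

#' Rasterize an ellipse into a binary mask (fixture generator)
#'
#' @param nrow,ncol image size in pixels.
#' @param center centre in pixels (row, col).
#' @param a,b semi-axes in pixels (equal for a disc).
#' @param angle rotation in radians.
#' @return binary integer matrix.
#' @export
raster_ellipse <- function(nrow, ncol, center = c(nrow / 2, ncol / 2),
                           a, b = a, angle = 0) {
  ij <- expand.grid(i = seq_len(nrow), j = seq_len(ncol))
  di <- ij$i - center[1L]; dj <- ij$j - center[2L]
  u <- cos(angle) * di + sin(angle) * dj
  v <- -sin(angle) * di + cos(angle) * dj
  matrix(as.integer((u / a)^2 + (v / b)^2 <= 1), nrow, ncol)
}
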