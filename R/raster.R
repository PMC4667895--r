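#' Lightweight planar raster grid
#'
#' A minimal single-band raster on a regular square grid in projected metric
#' coordinates. Values are stored as a numeric matrix with row 1 at the
#' *southern* edge (y increases with row index) and column 1 at the western
#' edge, so that matrix indices map directly onto planar coordinates.
#'
#' @param values numeric matrix of cell values.
#' @param origin numeric length-2: x and y (metres) of the grid's south-west
#'   corner (the outer corner of cell `[1, 1]`, not its centre).
#' @param cellsize cell edge length in metres.
#' @return an object of class `land_raster`.
#' @export
land_raster <- function(values, origin = c(0, 0), cellsize = 30) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("`origin` must be two finite numbers")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number")
  structure(
    list(values = values, origin = as.numeric(origin),
         cellsize = as.numeric(cellsize)),
    class = "land_raster")
}

#' @export
print.land_raster <- function(x, ...) {
  cat(sprintf("<land_raster> %d x %d cells, %g m resolution\n",
              nrow(x$values), ncol(x$values), x$cellsize))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] m\n",
              x$origin[1], x$origin[1] + ncol(x$values) * x$cellsize,
              x$origin[2], x$origin[2] + nrow(x$values) * x$cellsize))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values: [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.land_raster <- function(x) dim(x$values)

#' Coordinates of every cell centre
#'
#' @param r a [land_raster].
#' @return data.frame with columns `x`, `y`, `row`, `col`, in column-major
#'   cell order.
#' @export
cell_centres <- function(r) {
  stopifnot(inherits(r, "land_raster"))
  nr <- nrow(r$values); nc <- ncol(r$values)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  data.frame(x = r$origin[1] + (cols - 0.5) * r$cellsize,
             y = r$origin[2] + (rows - 0.5) * r$cellsize,
             row = rows, col = cols)
}

#' Map planar coordinates to raster row/column indices
#'
#' Points on the boundary between two cells belong to the cell with the
#' larger index (half-open cells), except the outermost edge which is closed
#' so that the full extent is covered.
#'
#' @param r a [land_raster].
#' @param x,y coordinate vectors in metres.
#' @return data.frame with integer columns `row`, `col`; NA for points
#'   outside the raster extent.
#' @export
cell_index <- function(r, x, y) {
  stopifnot(inherits(r, "land_raster"), length(x) == length(y))
  col <- floor((x - r$origin[1]) / r$cellsize) + 1L
  row <- floor((y - r$origin[2]) / r$cellsize) + 1L
  nr <- nrow(r$values); nc <- ncol(r$values)
  # points exactly on the far edge belong to the last cell
  col[x == r$origin[1] + nc * r$cellsize] <- nc
  row[y == r$origin[2] + nr * r$cellsize] <- nr
  bad <- col < 1L | col > nc | row < 1L | row > nr | !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Nearest-cell value lookup
#'
#' @param r a [land_raster].
#' @param x,y point coordinates in metres.
#' @param strict error (listing the offending indices) when a point falls
#'   outside the raster extent; otherwise return NA for such points.
#' @return numeric vector of cell values.
#' @export
extract_values <- function(r, x, y, strict = TRUE) {
  idx <- cell_index(r, x, y)
  off <- which(is.na(idx$row))
  if (strict && length(off))
    stop("points off the raster extent at positions: ",
         paste(utils::head(off, 10L), collapse = ", "),
         if (length(off) > 10L) " ..." else "")
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- r$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Slope and aspect from an elevation raster (Horn's method)
#'
#' Finite differences over the 3x3 neighbourhood (Horn 1981, the standard
#' DEM convention). Slope is returned in degrees; aspect is the azimuth of
#' the steepest *descent* direction (the direction the slope faces),
#' measured clockwise from north in `[0, 360)`. Cells with zero gradient
#' get aspect 0 and are flagged flat. Border cells use the one-cell-inward
#' replication of the grid.
#'
#' @param elevation a [land_raster] of elevation in metres, at least 3x3.
#' @return list with `slope` and `aspect` rasters (degrees) and `flat`,
#'   a logical matrix marking zero-gradient cells.
#' @export
derive_terrain <- function(elevation) {
  stopifnot(inherits(elevation, "land_raster"))
  z <- elevation$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3L || nc < 3L) stop("elevation raster must be at least 3x3")
  if (any(!is.finite(z))) stop("elevation must be finite")
  cs <- elevation$cellsize
  # replicate edges so the kernel is defined everywhere
  zp <- z[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  sh <- function(dr, dc) zp[seq_len(nr) + 1L + dr, seq_len(nc) + 1L + dc]
  # neighbours named by compass direction (row + 1 is north)
  nw <- sh( 1L, -1L); n_ <- sh( 1L, 0L); ne <- sh( 1L, 1L)
  w_ <- sh( 0L, -1L);                    e_ <- sh( 0L, 1L)
  sw <- sh(-1L, -1L); s_ <- sh(-1L, 0L); se <- sh(-1L, 1L)
  dzdx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * cs)
  dzdy <- ((ne + 2 * n_ + nw) - (se + 2 * s_ + sw)) / (8 * cs)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  # steepest descent direction is -grad z; azimuth clockwise from north
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  flat <- dzdx == 0 & dzdy == 0
  aspect[flat] <- 0
  list(slope  = land_raster(slope,  elevation$origin, cs),
       aspect = land_raster(aspect, elevation$origin, cs),
       flat   = flat)
}

#' Rasterize a buffered line network
#'
#' Marks every cell whose *centre* lies within `buffer_m` of any segment of
#' the network — the thalweg-mask construction used for the habitat layer
#' (a fixed buffer applied to the digitized drainage network).
#'
#' @param network list of line strings, each a 2-column matrix of x/y
#'   vertices in metres (same CRS as the grid).
#' @param grid a [land_raster] supplying the target grid.
#' @param buffer_m buffer distance in metres (default 25).
#' @return a binary [land_raster] (1 inside the buffer, 0 outside).
#' @export
buffer_network <- function(network, grid, buffer_m = 25) {
  stopifnot(inherits(grid, "land_raster"))
  if (!is.numeric(buffer_m) || buffer_m < 0) stop("`buffer_m` must be >= 0")
  out <- matrix(0, nrow(grid$values), ncol(grid$values))
  if (length(network) == 0L) {
    warning("empty line network: buffer raster is all zero")
    return(land_raster(out, grid$origin, grid$cellsize))
  }
  cc <- cell_centres(grid)
  d2min <- rep(Inf, nrow(cc))
  for (line in network) {
    if (!is.matrix(line) || ncol(line) != 2L)
      stop("each network line must be a 2-column matrix")
    nseg <- nrow(line) - 1L
    if (nseg < 1L) next
    for (s in seq_len(nseg)) {
      d2 <- .dist2_point_segment(cc$x, cc$y,
                                 line[s, 1], line[s, 2],
                                 line[s + 1L, 1], line[s + 1L, 2])
      d2min <- pmin(d2min, d2)
    }
  }
  inside <- d2min <= buffer_m^2
  out[cbind(cc$row, cc$col)] <- as.numeric(inside)
  land_raster(out, grid$origin, grid$cellsize)
}

# squared distance from points (px, py) to segment (ax, ay)-(bx, by)
.dist2_point_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  if (len2 == 0) return((px - ax)^2 + (py - ay)^2)
  t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2
}

#' Read / write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format for single-band rasters. `write_asc`
#' stores full double precision; the format's rows run north to south, so
#' the matrix is flipped on the way in and out.
#'
#' @param r a [land_raster].
#' @param path file path (conventionally `.asc`).
#' @return `read_asc` returns a [land_raster]; `write_asc` returns `path`
#'   invisibly.
#' @export
write_asc <- function(r, path) {
  stopifnot(inherits(r, "land_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", r$origin[1]),
    sprintf("yllcorner %.10g", r$origin[2]),
    sprintf("cellsize %.10g", r$cellsize),
    "NODATA_value -9999"), con)
  v <- r$values
  v[is.na(v)] <- -9999
  for (i in rev(seq_len(nrow(v))))
    writeLines(paste(formatC(v[i, ], format = "g", digits = 17),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  body <- lines[seq.int(i, length(lines))]
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  if (nrow(m) != hdr$nrows || ncol(m) != hdr$ncols)
    stop("ASCII grid body does not match its header dimensions")
  m[m == hdr$nodata_value] <- NA_real_
  land_raster(m[rev(seq_len(nrow(m))), , drop = FALSE],
              origin = c(hdr$xllcorner, hdr$yllcorner),
              cellsize = hdr$cellsize)
}
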