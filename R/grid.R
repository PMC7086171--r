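#' Build a triangular deme grid over a region
#'
#' Constructs the spatial substrate of the migration-surface model: a
#' triangular lattice of demes (vertices) connected by undirected edges.
#' In `planar` mode a regular triangular lattice with the requested spacing
#' is clipped to the region; in `spherical` mode an icosahedral geodesic
#' subdivision of the sphere is chosen so that its mean edge length is
#' closest to `spacing_km`, then clipped.  After clipping only the largest
#' connected component is retained, since disconnected fragments have
#' infinite resistance distance to the rest of the grid.
#'
#' @param region Either a numeric vector `c(xmin, xmax, ymin, ymax)`
#'   (a bounding box; lon/lat degrees in spherical mode, km in planar mode),
#'   a two-column matrix of polygon vertices (closed implicitly), or a path
#'   to a GeoJSON file containing a `Polygon` geometry.
#' @param spacing_km Nominal distance between neighbouring demes in km.
#'   Typical continental analyses use one of the presets in
#'   [grid_spacing_presets()].
#' @param mode `"planar"` (coordinates in km) or `"spherical"`
#'   (coordinates in degrees longitude/latitude).
#' @return An object of class `deme_graph`: a list with `vertices`
#'   (n x 2 matrix), `edges` (m x 2 integer matrix, `u < v`), `spacing_km`
#'   and `mode`.
#' @examples
#' g <- deme_grid(c(0, 1000, 0, 1000), spacing_km = 250, mode = "planar")
#' g
#' @seealso [assign_demes()], [resistance_distances()]
#' @export
deme_grid <- function(region, spacing_km, mode = c("planar", "spherical")) {
  mode <- match.arg(mode)
  if (!is.numeric(spacing_km) || length(spacing_km) != 1L || spacing_km <= 0)
    stop("'spacing_km' must be a single positive number")
  reg <- as_region(region)
  if (mode == "planar") {
    vv <- planar_lattice(reg, spacing_km)
  } else {
    vv <- geodesic_lattice(spacing_km)
  }
  keep <- region_contains(reg, vv$vertices)
  if (sum(keep) < 2L)
    stop("region too small: fewer than 2 demes at spacing ", spacing_km, " km")
  idx <- which(keep)
  remap <- integer(nrow(vv$vertices))
  remap[idx] <- seq_along(idx)
  e <- vv$edges[keep[vv$edges[, 1L]] & keep[vv$edges[, 2L]], , drop = FALSE]
  e <- cbind(remap[e[, 1L]], remap[e[, 2L]])
  verts <- vv$vertices[idx, , drop = FALSE]
  ## keep the largest connected component
  ig <- igraph::graph_from_edgelist(e, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, nrow(verts) - igraph::vcount(ig)))
  comp <- igraph::components(ig)
  main <- which.max(comp$csize)
  keep2 <- comp$membership == main
  if (sum(keep2) < 2L)
    stop("region too small: largest connected component has < 2 demes")
  idx2 <- which(keep2)
  remap2 <- integer(length(keep2))
  remap2[idx2] <- seq_along(idx2)
  e <- e[keep2[e[, 1L]] & keep2[e[, 2L]], , drop = FALSE]
  e <- cbind(remap2[e[, 1L]], remap2[e[, 2L]])
  e <- t(apply(e, 1L, sort))
  e <- unique(e[e[, 1L] != e[, 2L], , drop = FALSE])
  verts <- verts[idx2, , drop = FALSE]
  colnames(verts) <- if (mode == "planar") c("x", "y") else c("lon", "lat")
  structure(list(vertices = verts, edges = e, spacing_km = spacing_km,
                 mode = mode), class = "deme_graph")
}

#' Deme grid spacing presets
#'
#' Nominal inter-deme spacings (km) commonly used for global geodesic grids
#' at coarse, intermediate and fine resolution.
#' @return Named numeric vector of spacings in km.
#' @export
grid_spacing_presets <- function() {
  c(fine = 120, medium = 240, coarse = 500)
}

#' @export
print.deme_graph <- function(x, ...) {
  cat(sprintf("deme_graph: %d demes, %d edges, %s mode, spacing %g km\n",
              nrow(x$vertices), nrow(x$edges), x$mode, x$spacing_km))
  invisible(x)
}

#' Assign samples to their nearest deme
#'
#' Maps each sample to the nearest grid vertex: great-circle distance in
#' spherical mode, Euclidean distance in planar mode.  Ties are broken by
#' the lowest vertex index.  Samples outside the gridded region are still
#' assigned to the nearest retained vertex.
#'
#' @param coords Two-column matrix or data frame of sample coordinates
#'   (lon/lat degrees in spherical mode, km in planar mode). Row names or a
#'   `sample_id` column are used to name the result.
#' @param graph A [deme_grid()] object.
#' @return An object of class `deme_assignment`: a list with `vertex`
#'   (integer vector, one entry per sample) and `counts` (per-vertex sample
#'   counts, length = number of demes).
#' @export
assign_demes <- function(coords, graph) {
  stopifnot(inherits(graph, "deme_graph"))
  if (is.data.frame(coords)) {
    ids <- if ("sample_id" %in% names(coords)) as.character(coords$sample_id)
           else rownames(coords)
    cc <- c("lon", "lat")
    if (!all(cc %in% names(coords))) cc <- c("x", "y")
    if (!all(cc %in% names(coords)))
      coords <- as.matrix(coords[, 1:2]) else coords <- as.matrix(coords[, cc])
    if (!is.null(ids)) rownames(coords) <- ids
  }
  coords <- as.matrix(coords)
  bad <- !is.finite(coords[, 1L]) | !is.finite(coords[, 2L])
  if (any(bad)) {
    nm <- rownames(coords)[which(bad)[1L]]
    if (is.null(nm)) nm <- as.character(which(bad)[1L])
    stop("non-finite coordinate for sample ", nm)
  }
  if (nrow(graph$vertices) < 1L) stop("empty graph")
  d <- if (graph$mode == "spherical")
    great_circle_matrix(coords, graph$vertices)
  else
    plane_dist(coords, graph$vertices)
  vertex <- max.col(-d, ties.method = "first")
  names(vertex) <- rownames(coords)
  counts <- tabulate(vertex, nbins = nrow(graph$vertices))
  structure(list(vertex = vertex, counts = counts,
                 n_demes = nrow(graph$vertices)),
            class = "deme_assignment")
}

#' @export
print.deme_assignment <- function(x, ...) {
  cat(sprintf("deme_assignment: %d samples over %d of %d demes\n",
              length(x$vertex), sum(x$counts > 0L), x$n_demes))
  invisible(x)
}

#' Pairwise great-circle distance matrix
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param coords Two-column matrix of lon/lat in degrees.
#' @param coords2 Optional second coordinate set; defaults to `coords`.
#' @return Matrix of distances in km.
#' @export
great_circle_matrix <- function(coords, coords2 = coords) {
  coords <- as.matrix(coords); coords2 <- as.matrix(coords2)
  if (any(!is.finite(coords)) || any(!is.finite(coords2)))
    stop("non-finite coordinates")
  torad <- pi / 180
  lon1 <- coords[, 1L] * torad; lat1 <- coords[, 2L] * torad
  lon2 <- coords2[, 1L] * torad; lat2 <- coords2[, 2L] * torad
  dlat <- outer(lat1, lat2, `-`)
  dlon <- outer(lon1, lon2, `-`)
  a <- sin(dlat / 2)^2 + outer(cos(lat1), cos(lat2)) * sin(dlon / 2)^2
  a[a > 1] <- 1
  d <- 2 * 6371 * asin(sqrt(a))
  dimnames(d) <- list(rownames(coords), rownames(coords2))
  d
}

plane_dist <- function(a, b) {
  dx <- outer(a[, 1L], b[, 1L], `-`)
  dy <- outer(a[, 2L], b[, 2L], `-`)
  sqrt(dx * dx + dy * dy)
}

## ---- region handling -------------------------------------------------------

as_region <- function(region) {
  if (is.character(region) && length(region) == 1L) {
    gj <- jsonlite::read_json(region, simplifyVector = TRUE)
    geom <- if (!is.null(gj$geometry)) gj$geometry
            else if (!is.null(gj$features)) gj$features$geometry
            else gj
    coords <- geom$coordinates
    while (is.list(coords)) coords <- coords[[1L]]
    if (length(dim(coords)) == 3L) coords <- coords[1L, , ]
    region <- matrix(as.numeric(coords), ncol = 2L)
  }
  if (is.numeric(region) && is.null(dim(region)) && length(region) == 4L) {
    if (region[2L] <= region[1L] || region[4L] <= region[3L])
      stop("degenerate region bounding box")
    return(list(type = "bbox", bbox = region))
  }
  region <- as.matrix(region)
  if (ncol(region) != 2L || nrow(region) < 3L)
    stop("region must be a bbox c(xmin,xmax,ymin,ymax) or a polygon matrix")
  list(type = "polygon", poly = region,
       bbox = c(range(region[, 1L]), range(region[, 2L])))
}

region_contains <- function(reg, pts) {
  if (reg$type == "bbox") {
    b <- reg$bbox
    pts[, 1L] >= b[1L] & pts[, 1L] <= b[2L] &
      pts[, 2L] >= b[3L] & pts[, 2L] <= b[4L]
  } else {
    point_in_polygon(pts, reg$poly)
  }
}

## even-odd ray casting; points on an edge count as inside often enough for
## grid clipping purposes
point_in_polygon <- function(pts, poly) {
  x <- pts[, 1L]; y <- pts[, 2L]
  nx <- poly[, 1L]; ny <- poly[, 2L]
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- nx[i]; yi <- ny[i]; xj <- nx[j]; yj <- ny[j]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

## ---- lattice constructors --------------------------------------------------

planar_lattice <- function(reg, spacing) {
  b <- reg$bbox
  rowh <- spacing * sqrt(3) / 2
  ## overshoot by one row/col so clipping decides membership
  nr <- floor((b[4L] - b[3L]) / rowh) + 1L
  nc <- floor((b[2L] - b[1L]) / spacing) + 2L
  verts <- matrix(0, nr * nc, 2L)
  id <- function(r, c) (r - 1L) * nc + c
  for (r in seq_len(nr)) {
    off <- if (r %% 2L == 0L) spacing / 2 else 0
    verts[id(r, 1L):id(r, nc), 1L] <- b[1L] + (seq_len(nc) - 1L) * spacing + off
    verts[id(r, 1L):id(r, nc), 2L] <- b[3L] + (r - 1L) * rowh
  }
  edges <- list()
  k <- 1L
  for (r in seq_len(nr)) {
    ## same-row neighbours
    edges[[k]] <- cbind(id(r, seq_len(nc - 1L)), id(r, seq_len(nc - 1L) + 1L)); k <- k + 1L
    if (r < nr) {
      ## down-row neighbours: vertical plus the parity-dependent diagonal
      edges[[k]] <- cbind(id(r, seq_len(nc)), id(r + 1L, seq_len(nc))); k <- k + 1L
      if (r %% 2L == 1L) {
        cc <- seq_len(nc)[-1L]
        edges[[k]] <- cbind(id(r, cc), id(r + 1L, cc - 1L))
      } else {
        cc <- seq_len(nc - 1L)
        edges[[k]] <- cbind(id(r, cc), id(r + 1L, cc + 1L))
      }
      k <- k + 1L
    }
  }
  list(vertices = verts, edges = do.call(rbind, edges))
}

## class-I icosahedral subdivision with frequency chosen to match the
## requested spacing; vertices returned as lon/lat degrees
geodesic_lattice <- function(spacing_km) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  ## arc length between adjacent icosahedron vertices on a 6371 km sphere
  icosa_edge_km <- acos(sum(v[1, ] * v[12, ])) * 6371
  f <- max(1L, as.integer(round(icosa_edge_km / spacing_km)))
  key_env <- new.env(hash = TRUE, size = 20L * (f + 1L)^2)
  verts <- list(); nv <- 0L
  getv <- function(p) {
    p <- p / sqrt(sum(p^2))
    key <- paste(round(p, 9), collapse = ",")
    i <- key_env[[key]]
    if (is.null(i)) {
      nv <<- nv + 1L
      verts[[nv]] <<- p
      key_env[[key]] <- nv
      i <- nv
    }
    i
  }
  edges <- vector("list", nrow(faces))
  for (fi in seq_len(nrow(faces))) {
    a <- v[faces[fi, 1L], ]; bb <- v[faces[fi, 2L], ]; cc <- v[faces[fi, 3L], ]
    idx <- matrix(0L, f + 1L, f + 1L)
    for (i in 0:f) for (j in 0:(f - i))
      idx[i + 1L, j + 1L] <- getv(((f - i - j) * a + i * bb + j * cc) / f)
    ee <- list(); m <- 1L
    for (i in 0:f) for (j in 0:(f - i)) {
      if (i < f && j <= f - i - 1L) {
        ee[[m]] <- c(idx[i + 1L, j + 1L], idx[i + 2L, j + 1L]); m <- m + 1L
      }
      if (j < f - i) {
        ee[[m]] <- c(idx[i + 1L, j + 1L], idx[i + 1L, j + 2L]); m <- m + 1L
        ee[[m]] <- c(idx[i + 2L, j + 1L], idx[i + 1L, j + 2L]); m <- m + 1L
      }
    }
    edges[[fi]] <- do.call(rbind, ee)
  }
  vm <- do.call(rbind, verts)
  lon <- atan2(vm[, 2L], vm[, 1L]) * 180 / pi
  lat <- asin(pmin(1, pmax(-1, vm[, 3L]))) * 180 / pi
  e <- do.call(rbind, edges)
  e <- t(apply(e, 1L, sort))
  e <- unique(e)
  list(vertices = cbind(lon, lat), edges = e)
}

## ---- serialization ---------------------------------------------------------

#' Write or read a deme graph as JSON
#'
#' @param graph A `deme_graph` object.
#' @param path File path.
#' @return `read_deme_graph` returns a `deme_graph`; `write_deme_graph`
#'   returns `path` invisibly.
#' @export
write_deme_graph <- function(graph, path) {
  stopifnot(inherits(graph, "deme_graph"))
  obj <- list(vertices = unname(graph$vertices), edges = unname(graph$edges),
              spacing_km = graph$spacing_km, mode = graph$mode)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_deme_graph
#' @export
read_deme_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  verts <- matrix(as.numeric(obj$vertices), ncol = 2L)
  colnames(verts) <- if (obj$mode == "planar") c("x", "y") else c("lon", "lat")
  structure(list(vertices = verts,
                 edges = matrix(as.integer(obj$edges), ncol = 2L),
                 spacing_km = obj$spacing_km, mode = obj$mode),
            class = "deme_graph")
}
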