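#' Build a two-hemisphere icosphere surface mesh
#'
#' Constructs a triangulated sphere per hemisphere by recursive 4-fold
#' midpoint subdivision of an icosahedron with shared-edge deduplication,
#' projecting every new vertex radially onto the unit sphere. The two
#' hemispheres are identical icospheres distinguished by label; their
#' triangulations share no vertices, so the adjacency graph is connected
#' within a hemisphere and disconnected across hemispheres. Subdivision
#' level 6 reproduces the fsaverage6 resolution of 40,962 vertices per
#' hemisphere.
#'
#' @param level Non-negative integer subdivision level (0 = icosahedron).
#'   Levels above 7 are refused as a resolution guard.
#' @return An object of class `surface_mesh`: list with `vertices`
#'   (n x 3 unit-sphere coordinates, both hemispheres stacked, left
#'   hemisphere first), `faces` (m x 3 integer matrix of 1-based vertex
#'   indices), `hemisphere` (factor `"L"`/`"R"` per vertex), `level`,
#'   `n_vertices`, and `adjacency` (list of integer neighbor vectors).
#' @examples
#' mesh <- build_icosphere(1)
#' mesh$n_vertices  # 2 * (10 * 4^1 + 2) = 84
#' @export
build_icosphere <- function(level) {
  stopifnot(length(level) == 1, is.numeric(level), level >= 0,
            level == floor(level))
  if (level > 7) {
    stop("subdivision level ", level,
         " exceeds the resolution guard (max 7)", call. = FALSE)
  }
  hemi <- .icosphere_hemisphere(level)
  nv <- nrow(hemi$vertices)
  vertices <- rbind(hemi$vertices, hemi$vertices)
  faces <- rbind(hemi$faces, hemi$faces + nv)
  hemisphere <- factor(rep(c("L", "R"), each = nv), levels = c("L", "R"))
  mesh <- structure(
    list(vertices = vertices,
         faces = faces,
         hemisphere = hemisphere,
         level = as.integer(level),
         n_vertices = 2L * nv,
         adjacency = NULL),
    class = "surface_mesh")
  mesh$adjacency <- .face_adjacency(faces, mesh$n_vertices)
  mesh
}

# single-hemisphere icosphere: vertices on unit sphere, 1-based faces
.icosphere_hemisphere <- function(level) {
  t <- (1 + sqrt(5)) / 2
  v <- matrix(c(
    -1,  t,  0,   1,  t,  0,  -1, -t,  0,   1, -t,  0,
     0, -1,  t,   0,  1,  t,   0, -1, -t,   0,  1, -t,
     t,  0, -1,   t,  0,  1,  -t,  0, -1,  -t,  0,  1),
    ncol = 3, byrow = TRUE)
  v <- v / sqrt(rowSums(v^2))
  f <- matrix(c(
    1, 12,  6,   1,  6,  2,   1,  2,  8,   1,  8, 11,   1, 11, 12,
    2,  6, 10,   6, 12,  5,  12, 11,  3,  11,  8,  7,   8,  2,  9,
    4, 10,  5,   4,  5,  3,   4,  3,  7,   4,  7,  9,   4,  9, 10,
    5, 10,  6,   3,  5, 12,   7,  3, 11,   9,  7,  8,  10,  9,  2),
    ncol = 3, byrow = TRUE)
  for (l in seq_len(level)) {
    res <- .subdivide_once(v, f)
    v <- res$vertices
    f <- res$faces
  }
  list(vertices = v, faces = f)
}

# one midpoint-subdivision pass with shared-edge deduplication
.subdivide_once <- function(v, f) {
  nv <- nrow(v)
  # every edge (unordered) gets one midpoint vertex; key = i * (nv+1) + j
  e1 <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  lo <- pmin(e1[, 1], e1[, 2])
  hi <- pmax(e1[, 1], e1[, 2])
  key <- lo * (nv + 1) + hi
  ukey <- sort(unique(key))
  mid_idx <- nv + match(key, ukey)              # index of midpoint per face-edge
  ulo <- ukey %/% (nv + 1)
  uhi <- ukey %% (nv + 1)
  mids <- (v[ulo, , drop = FALSE] + v[uhi, , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))          # radial projection
  nf <- nrow(f)
  m12 <- mid_idx[seq_len(nf)]
  m23 <- mid_idx[nf + seq_len(nf)]
  m31 <- mid_idx[2L * nf + seq_len(nf)]
  faces <- rbind(
    cbind(f[, 1], m12, m31),
    cbind(f[, 2], m23, m12),
    cbind(f[, 3], m31, m23),
    cbind(m12, m23, m31))
  list(vertices = rbind(v, mids), faces = faces)
}

# adjacency list from face matrix
.face_adjacency <- function(faces, n_vertices) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  adj <- split(e[, 2], factor(e[, 1], levels = seq_len(n_vertices)))
  lapply(adj, function(x) sort(unique(x)))
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh: level", x$level, "icosphere,",
      x$n_vertices, "vertices (", x$n_vertices / 2L, "per hemisphere),",
      nrow(x$faces), "faces\n")
  invisible(x)
}

# igraph view of the mesh (cached on first use is unnecessary at desk scale)
mesh_graph <- function(mesh) {
  el <- cbind(rep(seq_along(mesh$adjacency), lengths(mesh$adjacency)),
              unlist(mesh$adjacency, use.names = FALSE))
  el <- el[el[, 1] < el[, 2], , drop = FALSE]
  igraph::graph_from_edgelist(el, directed = FALSE)
}

#' Geodesic hop distances from source vertices
#'
#' Breadth-first hop distance on the mesh adjacency graph from one or more
#' source vertices to every vertex. Hops never cross hemispheres because
#' the hemispheres are disconnected components.
#'
#' @param mesh A `surface_mesh`.
#' @param from Integer vector of source vertex indices.
#' @return Integer matrix `length(from)` x `n_vertices` of hop counts
#'   (`Inf` for the opposite hemisphere).
#' @export
mesh_hop_distance <- function(mesh, from) {
  stopifnot(all(from >= 1), all(from <= mesh$n_vertices))
  g <- mesh_graph(mesh)
  d <- igraph::distances(g, v = from, weights = NA)
  unname(d)
}

# vertices within `radius` hops of `center` (including it)
geodesic_disc <- function(mesh, center, radius) {
  d <- mesh_hop_distance(mesh, center)
  which(d[1, ] <= radius)
}

# deterministic farthest-point sampling of n anchor vertices on hop metric,
# alternating hemispheres so zones spread over both
place_zone_anchors <- function(mesh, n_zones) {
  g <- mesh_graph(mesh)
  anchors <- 1L                                  # first left-hemisphere vertex
  while (length(anchors) < n_zones) {
    d <- igraph::distances(g, v = anchors, weights = NA)
    dmin <- apply(d, 2, min)
    dmin[!is.finite(dmin)] <- mesh$n_vertices    # other hemisphere: very far
    cand <- which(dmin == max(dmin))
    anchors <- c(anchors, cand[1])               # lowest index tie-break
  }
  sort(anchors)
}

# n_zones disjoint geodesic discs; errors if they cannot be placed disjointly
place_zones <- function(mesh, n_zones, zone_radius) {
  anchors <- place_zone_anchors(mesh, n_zones)
  d <- mesh_hop_distance(mesh, anchors)
  zone_of <- rep(NA_integer_, mesh$n_vertices)
  for (z in seq_len(n_zones)) {
    inz <- which(d[z, ] <= zone_radius)
    clash <- inz[!is.na(zone_of[inz])]
    if (length(clash) > 0) {
      stop("zones cannot be placed disjointly: zone ", z,
           " overlaps an earlier zone at radius ", zone_radius, call. = FALSE)
    }
    zone_of[inz] <- z
  }
  list(n_zones = n_zones, anchors = anchors, zone_of = zone_of,
       radius = zone_radius,
       members = lapply(seq_len(n_zones), function(z) which(zone_of == z)))
}
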