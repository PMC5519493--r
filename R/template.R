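# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic 31-bit seed derivation from a master seed and integer tags
derive_seed <- function(master, ...) {
  s <- as.double(master) %% 2147483563
  for (tag in list(...)) {
    s <- (s * 69069 + as.double(tag) + 1) %% 2147483563
  }
  as.integer(s + 1)
}

# BFS hop distances from `from` restricted to the vertex set `within`
restricted_hops <- function(adjacency, from, within) {
  inside <- logical(length(adjacency))
  inside[within] <- TRUE
  d <- rep(Inf, length(adjacency))
  d[from] <- 0
  frontier <- from
  while (length(frontier) > 0) {
    nxt <- unique(unlist(adjacency[frontier], use.names = FALSE))
    nxt <- nxt[inside[nxt] & d[nxt] == Inf]
    d[nxt] <- d[frontier[1]] + 1   # frontier is a single BFS level
    frontier <- nxt
  }
  d
}

#' Plant interdigitated network parcels across geodesic zones
#'
#' Lays out `n_zones` disjoint geodesic-disc zones on the mesh
#' (deterministic farthest-point anchors) and, inside every zone, one
#' parcel per network. Parcel anchors are the zone anchor and its
#' immediate neighbors, so parcels of different networks lie side by
#' side: disjoint vertex supports that share at least one mesh edge.
#' With `jitter_steps > 0`, each parcel anchor is displaced by a
#' subject-specific random walk of at most `jitter_steps` hops inside
#' its zone (moves that would land on another network's anchor are
#' rejected), emulating between-subject variation in region locations.
#'
#' @param mesh A `surface_mesh`.
#' @param n_networks Number of planted networks (>= 1).
#' @param n_zones Number of zones; every zone receives one parcel of
#'   every network.
#' @param parcel_radius Parcel radius in geodesic hops.
#' @param jitter_steps Maximum anchor displacement in hops (0 = none).
#' @param subject_seed RNG seed for the jitter walk; unused when
#'   `jitter_steps = 0`.
#' @param zone_radius Zone disc radius in hops (default
#'   `2 * parcel_radius`, enough to hold the displaced parcels).
#' @return A `network_template`: `assignment` (integer per vertex,
#'   0 = background), `n_networks`, `zones`, `anchors` (zone x network
#'   matrix of parcel anchor vertices), `jitter_record` (zone x network
#'   hop displacements), plus layout parameters.
#' @export
plant_networks <- function(mesh, n_networks, n_zones, parcel_radius = 1,
                           jitter_steps = 0, subject_seed = 1,
                           zone_radius = 2 * parcel_radius) {
  stopifnot(n_networks >= 1, n_zones >= 1, parcel_radius >= 1,
            jitter_steps >= 0)
  zones <- place_zones(mesh, n_zones, zone_radius)
  base_anchors <- matrix(NA_integer_, n_zones, n_networks)
  for (z in seq_len(n_zones)) {
    a <- zones$anchors[z]
    nb <- mesh$adjacency[[a]]
    nb <- nb[nb %in% zones$members[[z]]]
    if (length(nb) < n_networks - 1) {
      stop("zone ", z, " cannot host ", n_networks,
           " adjacent parcel anchors", call. = FALSE)
    }
    base_anchors[z, ] <- c(a, nb[seq_len(n_networks - 1)])
  }
  anchors <- base_anchors
  jitter_record <- matrix(0L, n_zones, n_networks)
  if (jitter_steps > 0) {
    with_seed(subject_seed, {
      for (z in seq_len(n_zones)) {
        memb <- zones$members[[z]]
        for (k in seq_len(n_networks)) {
          pos <- base_anchors[z, k]
          n_steps <- sample.int(jitter_steps + 1L, 1L) - 1L  # 0..jitter_steps
          for (s in seq_len(n_steps)) {
            nb <- mesh$adjacency[[pos]]
            nb <- nb[nb %in% memb]
            nb <- nb[!(nb %in% anchors[z, seq_len(n_networks) != k])]
            if (length(nb) == 0) break
            pos <- nb[sample.int(length(nb), 1L)]
          }
          anchors[z, k] <- pos
          jitter_record[z, k] <-
            as.integer(restricted_hops(mesh$adjacency,
                                       base_anchors[z, k], memb)[pos])
        }
      }
    })
  }
  assignment <- integer(mesh$n_vertices)
  for (z in seq_len(n_zones)) {
    memb <- zones$members[[z]]
    d <- sapply(seq_len(n_networks), function(k)
      restricted_hops(mesh$adjacency, anchors[z, k], memb))
    for (v in memb) {
      dv <- d[v, ]
      k <- which.min(dv)                          # ties -> lower network id
      if (is.finite(dv[k]) && dv[k] <= parcel_radius) assignment[v] <- k
    }
  }
  structure(
    list(assignment = assignment,
         n_networks = as.integer(n_networks),
         zones = zones,
         anchors = anchors,
         jitter_record = jitter_record,
         parcel_radius = parcel_radius,
         jitter_steps = as.integer(jitter_steps),
         subject_seed = subject_seed,
         n_vertices = mesh$n_vertices),
    class = "network_template")
}

#' @export
print.network_template <- function(x, ...) {
  cat("network_template:", x$n_networks, "networks x",
      x$zones$n_zones, "zones;",
      sum(x$assignment > 0), "of", x$n_vertices, "vertices assigned;",
      "jitter", x$jitter_steps, "hops\n")
  invisible(x)
}

# vertex supports per network
template_support <- function(template, network) {
  which(template$assignment == network)
}
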