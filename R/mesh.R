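## Triangle-mesh primitives shared by every stage of the pipeline.
## Meshes are plain lists: vertices (n x 3, mm), triangles (m x 3 integer,
## consistently outward-oriented).

#' Unit icosahedron
#' @noRd
icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c(1,  t,  0), c(-1, -t,  0), c(1, -t,  0),
    c( 0, -1,  t), c(0,  1,  t), c( 0, -1, -t), c(0,  1, -t),
    c( t,  0, -1), c(t,  0,  1), c(-t,  0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, triangles = f)
}

#' Subdivide each triangle into four and project back to the unit sphere
#' @noRd
subdivide_sphere <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$triangles
  nv <- nrow(v)
  ## unique edge midpoints
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  uk <- !duplicated(key)
  eu <- e[uk, , drop = FALSE]
  mid <- (v[eu[, 1], ] + v[eu[, 2], ]) / 2
  mid <- mid / sqrt(rowSums(mid^2))
  midx <- nv + match(key, key[uk])
  m12 <- midx[seq_len(nrow(f))]
  m23 <- midx[nrow(f) + seq_len(nrow(f))]
  m31 <- midx[2 * nrow(f) + seq_len(nrow(f))]
  f2 <- rbind(
    cbind(f[, 1], m12, m31),
    cbind(f[, 2], m23, m12),
    cbind(f[, 3], m31, m23),
    cbind(m12, m23, m31))
  list(vertices = rbind(v, mid), triangles = f2)
}

#' Unit icosphere at a given subdivision level
#' @noRd
icosphere <- function(level) {
  m <- icosahedron()
  for (i in seq_len(level)) m <- subdivide_sphere(m)
  m
}

#' Per-triangle areas (same length unit squared as the vertices)
#' @noRd
triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c3 <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a
  w <- c3 - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Per-triangle unit normals
#' @noRd
triangle_normals <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c3 <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a
  w <- c3 - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  cr / pmax(sqrt(rowSums(cr^2)), .Machine$double.eps)
}

#' Barycentric (one-ring / 3) vertex areas
#' @noRd
vertex_areas <- function(vertices, triangles) {
  ta <- triangle_areas(vertices, triangles)
  va <- numeric(nrow(vertices))
  for (k in 1:3) {
    acc <- tapply(ta, triangles[, k], sum)
    va[as.integer(names(acc))] <- va[as.integer(names(acc))] + acc
  }
  va / 3
}

#' Unique undirected edges with incident-triangle counts
#' @return list(edges = 2-col matrix, count = times each edge occurs)
#' @noRd
mesh_edges <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  tab <- table(key)
  uk <- !duplicated(key)
  eu <- e[uk, , drop = FALSE]
  cnt <- as.integer(tab[key[uk]])
  list(edges = eu, count = cnt)
}

#' Ordered boundary loops (each a closed ring of vertex indices)
#'
#' Boundary edges are edges incident to exactly one triangle.
#' @noRd
boundary_loops <- function(triangles) {
  me <- mesh_edges(triangles)
  be <- me$edges[me$count == 1L, , drop = FALSE]
  if (nrow(be) == 0) return(list())
  ## adjacency restricted to boundary edges: every boundary vertex has 2
  nbr <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  deg <- lengths(nbr)
  if (any(deg != 2L))
    stop("non-manifold boundary: vertex with boundary degree != 2")
  loops <- list()
  seen <- logical(max(be))
  for (i in seq_len(nrow(be))) {
    start <- be[i, 1]
    if (seen[start]) next
    prev <- start
    cur <- be[i, 2]
    seen[start] <- TRUE
    loop <- start
    while (cur != start) {
      seen[cur] <- TRUE
      loop <- c(loop, cur)
      nb <- nbr[[as.character(cur)]]
      nxt <- nb[nb != prev][1]
      prev <- cur
      cur <- nxt
    }
    loops[[length(loops) + 1]] <- loop
  }
  loops
}

#' Vertex-adjacency graph weighted by edge length (igraph)
#' @noRd
mesh_graph <- function(vertices, triangles) {
  me <- mesh_edges(triangles)
  e <- me$edges
  w <- sqrt(rowSums((vertices[e[, 1], , drop = FALSE] -
                       vertices[e[, 2], , drop = FALSE])^2))
  igraph::graph_from_edgelist(e, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
}

#' Geodesic (graph) distances from a set of source vertices to all vertices
#'
#' Returns the minimum over sources, in mm. Approximates surface geodesic
#' distance by shortest paths along mesh edges.
#' @noRd
geodesic_distance <- function(surface_or_graph, sources,
                              vertices = NULL, triangles = NULL) {
  g <- if (igraph::is_igraph(surface_or_graph)) surface_or_graph
       else mesh_graph(surface_or_graph$vertices, surface_or_graph$triangles)
  d <- igraph::distances(g, v = sources)
  if (length(sources) == 1) as.numeric(d) else apply(d, 2, min)
}

#' Connected components of a vertex subset (edge-connected)
#'
#' @param triangles triangle index matrix of the full mesh
#' @param keep logical per vertex; components are computed on the subgraph
#'   induced by TRUE vertices.
#' @return integer per vertex: component id (1-based, by decreasing size),
#'   NA outside the subset.
#' @noRd
vertex_components <- function(n_vertices, triangles, keep) {
  me <- mesh_edges(triangles)
  e <- me$edges
  e <- e[keep[e[, 1]] & keep[e[, 2]], , drop = FALSE]
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_vertices - igraph::gorder(g)))
  comp <- igraph::components(g)$membership
  comp[!keep] <- NA
  ids <- sort(table(comp), decreasing = TRUE)
  out <- match(comp, as.integer(names(ids)))
  out
}

#' Connected components of an element (triangle) subset
#'
#' Elements are adjacent when they share an edge.
#' @return integer per element: component id by decreasing count, NA outside.
#' @noRd
element_components <- function(triangles, keep) {
  m <- nrow(triangles)
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tri_id <- rep(seq_len(m), 3)
  key <- paste(e[, 1], e[, 2])
  ord <- order(key)
  key <- key[ord]
  tri_id <- tri_id[ord]
  same <- key[-1] == key[-length(key)]
  pairs <- cbind(tri_id[c(same, FALSE)], tri_id[c(FALSE, same)])
  pairs <- pairs[keep[pairs[, 1]] & keep[pairs[, 2]], , drop = FALSE]
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (nrow(pairs) > 0) g <- igraph::add_edges(g, t(pairs))
  comp <- igraph::components(g)$membership
  comp[!keep] <- NA
  ids <- sort(table(comp), decreasing = TRUE)
  match(comp, as.integer(names(ids)))
}

#' Regular triangulated strip in the x-y plane
#'
#' @param length_mm,width_mm strip dimensions
#' @param h target edge length (mm)
#' @return mesh list with vertices (z = 0) and triangles; fibers along +x.
#' @noRd
strip_mesh <- function(length_mm = 40, width_mm = 10, h = 0.5) {
  nx <- max(2L, as.integer(round(length_mm / h)) + 1L)
  ny <- max(2L, as.integer(round(width_mm / h)) + 1L)
  xs <- seq(0, length_mm, length.out = nx)
  ys <- seq(0, width_mm, length.out = ny)
  v <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  idx <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  f <- rbind(
    cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
    cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  fib <- matrix(rep(c(1, 0, 0), each = nrow(f)), ncol = 3)
  list(vertices = v, triangles = f, fiber = fib,
       nx = nx, ny = ny, length_mm = length_mm, width_mm = width_mm)
}
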