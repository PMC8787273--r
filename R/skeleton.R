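#' Medial-axis skeleton of a binary mask
#'
#' Zhang-Suen morphological thinning down to an (approximately) one pixel
#' wide 8-connected medial line. This is the axis along which local fibre
#' widths are read off the Euclidean distance transform.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Logical matrix of the same shape with the skeleton set.
#' @seealso [skeleton_path()], [width_profile()]
#' @export
skeletonize <- function(mask) {
  if (is.null(dim(mask))) stop("`mask` must be a matrix")
  .thin_zs(matrix(as.logical(mask > 0), nrow(mask), ncol(mask)))
}

#' Longest geodesic path through a skeleton
#'
#' Orders skeleton pixels along the skeleton's graph diameter (double
#' breadth-first search over the 8-connected pixel graph). Side branches of
#' the thinning are dropped, leaving the main medial axis from tip to tip.
#'
#' @param skeleton Logical matrix as returned by [skeletonize()].
#' @return Integer matrix with columns `row`, `col`, ordered along the path.
#' @export
skeleton_path <- function(skeleton) {
  idx <- which(skeleton, arr.ind = TRUE)
  colnames(idx) <- c("row", "col")
  n <- nrow(idx)
  if (n <= 2L) return(idx)

  # vectorised 8-neighbour edge list over a positional key
  key <- idx[, "row"] + (idx[, "col"] - 1) * (max(idx[, "row"]) + 2)
  offs <- cbind(
    dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
    dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  )
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb_key <- (idx[, "row"] + offs[k, "dr"]) +
      (idx[, "col"] + offs[k, "dc"] - 1) * (max(idx[, "row"]) + 2)
    hit <- match(nb_key, key)
    ok <- !is.na(hit)
    from <- c(from, which(ok)); to <- c(to, hit[ok])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }

  # keep the largest connected piece, then take its diameter path
  comp <- igraph::components(g)
  main <- which(comp$membership == which.max(comp$csize))
  d1 <- igraph::distances(g, v = main[1], to = main)
  u <- main[which.max(d1)]
  d2 <- igraph::distances(g, v = u, to = main)
  v <- main[which.max(d2)]
  path <- igraph::shortest_paths(g, from = u, to = v)$vpath[[1]]
  idx[as.integer(path), , drop = FALSE]
}
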