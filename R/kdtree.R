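# 2D k-d tree for nearest-neighbor queries. Built by median split with
# alternating axes; the query prunes subtrees by the splitting-plane
# distance. Distances use the same plain Euclidean arithmetic as the
# brute-force oracle the tests compare against, so agreement is exact.

kdtree_build <- function(points, idx = seq_len(nrow(points)), depth = 0L) {
  if (length(idx) == 0) return(NULL)
  axis <- depth %% 2L + 1L
  ord <- idx[order(points[idx, axis])]
  mid <- (length(ord) + 1L) %/% 2L
  list(
    idx = ord[mid],
    axis = axis,
    split = points[ord[mid], axis],
    left = kdtree_build(points, ord[seq_len(mid - 1L)], depth + 1L),
    right = kdtree_build(points, ord[seq_len(length(ord) - mid) + mid], depth + 1L)
  )
}

kdtree_nn <- function(tree, points, q) {
  best <- list(idx = 0L, d2 = Inf)
  recurse <- function(node) {
    if (is.null(node)) return(invisible())
    p <- points[node$idx, ]
    d2 <- (p[1] - q[1])^2 + (p[2] - q[2])^2
    if (d2 < best$d2 || (d2 == best$d2 && node$idx < best$idx)) {
      best <<- list(idx = node$idx, d2 = d2)
    }
    diffax <- q[node$axis] - node$split
    first <- if (diffax <= 0) node$left else node$right
    second <- if (diffax <= 0) node$right else node$left
    recurse(first)
    if (diffax^2 <= best$d2) recurse(second)
  }
  recurse(tree)
  list(idx = best$idx, dist = sqrt(best$d2))
}

# Nearest PCNA focus for each query point; returns data frame (index, dist).
nearest_neighbors <- function(query_xy, ref_xy) {
  ref_xy <- as.matrix(ref_xy)
  tree <- kdtree_build(ref_xy)
  res <- t(vapply(seq_len(nrow(query_xy)), function(i) {
    nn <- kdtree_nn(tree, ref_xy, as.numeric(query_xy[i, ]))
    c(nn$idx, nn$dist)
  }, numeric(2)))
  data.frame(index = as.integer(res[, 1]), dist = res[, 2])
}
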