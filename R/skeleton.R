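# Binary skeletonization (Zhang-Suen thinning) and skeleton path length.
# Z-lines are curvilinear: each connected component's length is the longest
# geodesic path through its 1-px skeleton, with sqrt(2) weighting for
# diagonal steps, plus one pixel so that a straight n-pixel run measures n
# pixels end to end.

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Thin a binary image to a 1-pixel skeleton
#'
#' Zhang-Suen two-subiteration thinning; preserves 8-connectivity.
#'
#' @param mask logical or 0/1 matrix
#' @return integer 0/1 matrix of the same shape
#' @export
thin_binary <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # clockwise neighbours starting north: P2..P9
      p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1); p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1);  p9 <- shift_mat(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (sub == 1) {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Adjacent skeleton-pixel pairs with step weights (1 orthogonal, sqrt(2)
# diagonal). idx is the vector of linear indices of skeleton pixels.
skeleton_edges <- function(skel) {
  nr <- nrow(skel)
  idx <- which(skel != 0)
  if (!length(idx)) return(NULL)
  node <- integer(length(skel))
  node[idx] <- seq_along(idx)
  r <- ((idx - 1) %% nr) + 1
  co <- ((idx - 1) %/% nr) + 1
  from <- integer(0); to <- integer(0); w <- numeric(0)
  offs <- list(c(1, 0, 1), c(0, 1, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))
  for (o in offs) {
    rr <- r + o[1]; cc <- co + o[2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= ncol(skel)
    j <- (cc[ok] - 1) * nr + rr[ok]
    hit <- node[j] > 0
    from <- c(from, node[idx[ok]][hit])
    to <- c(to, node[j][hit])
    w <- c(w, rep(o[3], sum(hit)))
  }
  list(n = length(idx), from = from, to = to, w = w)
}

dijkstra_far <- function(edges, src) {
  n <- edges$n
  adj_from <- c(edges$from, edges$to)
  adj_to <- c(edges$to, edges$from)
  adj_w <- c(edges$w, edges$w)
  dist <- rep(Inf, n); dist[src] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    sel <- adj_from == u
    v <- adj_to[sel]
    nd <- dist[u] + adj_w[sel]
    upd <- nd < dist[v]
    dist[v[upd]] <- nd[upd]
  }
  dist
}

#' Geodesic length of a skeletonized component
#'
#' Longest geodesic path through the skeleton in pixels (orthogonal steps 1,
#' diagonal steps sqrt(2)) plus one pixel for the end caps. For unbranched
#' skeletons (every pixel with at most 2 neighbours) the path is the sum of
#' all step weights; branched skeletons use a double-sweep farthest-point
#' search, exact on trees.
#'
#' @param skel 0/1 skeleton matrix (one connected component)
#' @return length in pixels
#' @export
skeleton_path_px <- function(skel) {
  edges <- skeleton_edges(skel)
  if (is.null(edges)) return(0)
  if (edges$n == 1) return(1)
  deg <- tabulate(c(edges$from, edges$to), nbins = edges$n)
  if (max(deg) <= 2) {
    return(sum(edges$w) + 1)
  }
  d1 <- dijkstra_far(edges, 1L)
  d1[!is.finite(d1)] <- -1
  far <- which.max(d1)
  d2 <- dijkstra_far(edges, far)
  d2[!is.finite(d2)] <- -1
  max(d2) + 1
}
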