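# Neighbor-joining on a complete distance matrix, with deterministic
# tie-breaking and non-negative branch lengths.

#' Neighbor-joining tree
#'
#' Standard agglomeration on the Q-criterion. Ties in the minimal Q pick
#' the lexicographically lowest index pair; negative branch-length
#' estimates are clamped to zero (noted in the `"clamped"` attribute).
#'
#' @param D symmetric distance matrix with taxon dimnames (>= 3 taxa,
#'   complete)
#' @return an unrooted `ape::phylo` with branch lengths
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) abort("neighbor joining needs >= 3 taxa")
  if (any(is.na(D))) abort("distance matrix is incomplete")
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  # node ids: tips 1..n, internals n+1 .. 2n-2 (root = last created)
  active <- seq_len(n)
  next_id <- 2L * n - 2L   # create internals downward, root becomes n+1
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric()
  clamped <- FALSE
  W <- D
  while (length(active) > 3L) {
    r <- length(active)
    rs <- rowSums(W)
    Q <- (r - 2) * W - outer(rs, rs, `+`)
    diag(Q) <- Inf
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- W[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- W[i, j] - li
    if (li < 0 || lj < 0) clamped <- TRUE
    li <- max(li, 0); lj <- max(lj, 0)
    new <- next_id
    next_id <- next_id - 1L
    edges <- rbind(edges, c(new, active[i]), c(new, active[j]))
    lens <- c(lens, li, lj)
    dk <- (W[i, -c(i, j)] + W[j, -c(i, j)] - W[i, j]) / 2
    W <- W[-c(i, j), -c(i, j), drop = FALSE]
    W <- rbind(cbind(W, dk), c(dk, 0))
    active <- c(active[-c(i, j)], new)
  }
  # final three-point configuration
  d12 <- W[1, 2]; d13 <- W[1, 3]; d23 <- W[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  if (min(l1, l2, l3) < 0) clamped <- TRUE
  center <- next_id
  edges <- rbind(edges, c(center, active[1]), c(center, active[2]),
                 c(center, active[3]))
  lens <- c(lens, max(l1, 0), max(l2, 0), max(l3, 0))
  # renumber internals so that the center (root) is n+1 and numbering is
  # preorder, as ape expects
  internal_old <- sort(unique(edges[edges > n]))
  kids <- split(seq_len(nrow(edges)), edges[, 1])
  newnum <- integer(2L * n - 2L)
  counter <- n
  assign_num <- function(node) {
    counter <<- counter + 1L
    newnum[node] <<- counter
    for (e in kids[[as.character(node)]]) {
      child <- edges[e, 2]
      if (child > n) assign_num(child)
    }
  }
  assign_num(center)
  remap <- function(v) ifelse(v > n, newnum[v], v)
  phy <- structure(
    list(edge = cbind(remap(edges[, 1]), remap(edges[, 2])),
         edge.length = lens, tip.label = labels,
         Nnode = length(internal_old)),
    class = "phylo", order = "unknown"
  )
  phy <- ape::reorder.phylo(phy, "cladewise")
  attr(phy, "clamped") <- clamped
  phy
}
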