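# children lists keyed by node id
node_children <- function(rs) {
  split(rs$segments$dist, factor(rs$segments$prox,
                                 levels = rs$nodes$id))
}

#' Root-system traits
#'
#' Morphological and topological summary of a root system: total length,
#' root counts per branching order, maximum rooting depth and horizontal
#' width, and the Fitter topological indices computed on the link tree
#' (degree-two nodes contracted): magnitude (number of exterior links),
#' altitude (longest collar-to-tip path in links) and total exterior path
#' length (sum of tip link-depths).
#'
#' @param rs a \code{root_system}
#' @return a list of class \code{trait_vector}
#' @export
root_traits <- function(rs) {
  nd <- rs$nodes; sg <- rs$segments
  len <- segment_lengths(rs)
  per_order <- if (nrow(sg))
    table(rs$roots$order[!duplicated(rs$roots$root_id)]) else table(integer(0))
  kids <- node_children(rs)
  nkids <- vapply(kids, length, integer(1))
  names(nkids) <- rs$nodes$id
  tips <- nd$id[nkids[as.character(nd$id)] == 0L & nd$id != 1L]
  # link depth: +1 when the edge leaves the collar or a branching node
  link_depth <- rep(NA_real_, max(nd$id))
  link_depth[1L] <- 0
  ord <- traversal_order(rs)
  parent <- rep(NA_integer_, max(nd$id))
  parent[sg$dist] <- sg$prox
  for (v in ord[-1]) {
    u <- parent[v]
    link_depth[v] <- link_depth[u] +
      as.numeric(u == 1L || nkids[as.character(u)] >= 2L)
  }
  tip_depths <- link_depth[tips]
  structure(list(
    total_length = sum(len),
    n_roots_per_order = per_order,
    max_depth = if (nrow(nd)) max(-nd$z) else 0,
    width = if (nrow(nd)) max(diff(range(nd$x)), diff(range(nd$y))) else 0,
    magnitude = length(tips),
    altitude = if (length(tips)) max(tip_depths) else 0,
    exterior_path_length = sum(tip_depths)),
    class = "trait_vector")
}

# topological order from the collar outward
traversal_order <- function(rs) {
  sg <- rs$segments
  ord <- integer(0)
  frontier <- 1L
  kids <- split(sg$dist, sg$prox)
  while (length(frontier)) {
    ord <- c(ord, frontier)
    frontier <- unlist(kids[as.character(frontier)], use.names = FALSE)
  }
  ord
}

#' Vertical root distribution and rooting-depth index
#'
#' Bins root length by depth (d = |z|, below the soil surface), forms the
#' relative cumulative root length profile
#' \eqn{Y(d) = \sum_{i \le d} RLD(i) / \sum_i RLD(i)} and fits the
#' distribution index \eqn{\beta} of \eqn{Y(d) = 1 - \beta^d} by nonlinear
#' least squares; large \eqn{\beta} corresponds to deep rooting.
#'
#' @param rs a \code{root_system}
#' @param bin depth bin width (cm)
#' @return a list of class \code{depth_profile} with \code{d} (bin upper
#'   edges, cm), \code{rld} (root length per bin, cm), \code{Y}, and the
#'   fitted \code{beta}
#' @export
depth_distribution <- function(rs, bin = 1) {
  stopifnot(bin > 0)
  nd <- rs$nodes; sg <- rs$segments
  if (nrow(sg) == 0) stop("root system has no segments")
  len <- segment_lengths(rs)
  iz <- -nd$z[match(sg$prox, nd$id)]
  jz <- -nd$z[match(sg$dist, nd$id)]
  dmax <- max(c(iz, jz), 0) + bin
  edges <- seq(0, ceiling(dmax / bin) * bin, by = bin)
  nbin <- length(edges) - 1L
  rld <- numeric(nbin)
  lo <- pmin(iz, jz); hi <- pmax(iz, jz)
  for (s in seq_along(len)) {
    if (hi[s] <= 0) next                      # above the surface
    a <- max(lo[s], 0); b <- hi[s]
    k1 <- max(1L, findInterval(a, edges, rightmost.closed = TRUE))
    k2 <- max(1L, findInterval(b - 1e-12, edges, rightmost.closed = TRUE))
    span <- hi[s] - lo[s]
    for (k in k1:k2) {
      ov <- max(0, min(b, edges[k + 1]) - max(a, edges[k]))
      rld[k] <- rld[k] + if (span > 1e-12) len[s] * ov / span
                         else len[s] * (k == k1)
    }
  }
  keep <- seq_len(max(which(rld > 0), 1L))
  rld <- rld[keep]
  d <- edges[keep + 1L]
  Y <- cumsum(rld) / sum(rld)
  beta <- fit_beta(d, Y)
  structure(list(d = d, rld = rld, Y = Y, beta = beta, bin = bin),
            class = "depth_profile")
}

#' Fit the rooting-depth distribution index
#'
#' Nonlinear least squares fit of \eqn{Y(d) = 1 - \beta^d} with
#' \eqn{\beta} constrained to (0, 1).
#'
#' @param d depths (cm)
#' @param Y relative cumulative root fraction at \code{d}
#' @return the fitted \eqn{\beta}
#' @export
fit_beta <- function(d, Y) {
  stopifnot(length(d) == length(Y), all(is.finite(d)), all(is.finite(Y)))
  if (length(d) < 2) {
    warning("degenerate depth profile: beta at boundary")
    return(1e-8)
  }
  # log-linear estimate seeds the nonlinear fit
  pos <- Y < 1 - 1e-12
  start <- if (sum(pos) >= 2)
    min(max(exp(sum(d[pos] * log(1 - Y[pos])) / sum(d[pos]^2)), 1e-6),
        1 - 1e-9)
  else 0.9
  fit <- minpack.lm::nlsLM(Y ~ 1 - beta^d,
                           data = data.frame(d = d, Y = Y),
                           start = list(beta = start),
                           lower = 1e-8, upper = 1 - 1e-12,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  unname(stats::coef(fit)[["beta"]])
}

#' Persistence barcode of a root system
#'
#' Computes the H0 persistence barcode of the superlevel-set filtration of
#' the geodesic (along-root) distance from the collar.  Each root tip
#' contributes one bar: it is born at the tip's geodesic distance and dies
#' at the geodesic distance of the junction where its branch merges into a
#' branch with a farther tip (elder rule); the globally farthest tip's bar
#' dies at 0.  Ties are broken deterministically by node id.
#'
#' @param rs a \code{root_system}
#' @return a data frame of class \code{barcode} with columns \code{birth},
#'   \code{death} (cm, birth >= death) and \code{tip} (node id)
#' @export
persistence_barcode <- function(rs) {
  nd <- rs$nodes; sg <- rs$segments
  len <- segment_lengths(rs)
  maxid <- max(nd$id)
  parent <- rep(NA_integer_, maxid)
  parent[sg$dist] <- sg$prox
  elen <- rep(NA_real_, maxid)
  elen[sg$dist] <- len
  gdist <- rep(NA_real_, maxid)
  gdist[1L] <- 0
  ord <- traversal_order(rs)
  for (v in ord[-1]) gdist[v] <- gdist[parent[v]] + elen[v]
  kids <- split(sg$dist, sg$prox)
  nkid <- vapply(kids, length, integer(1))
  tips <- nd$id[!(nd$id %in% sg$prox) & nd$id != 1L]
  if (!length(tips))
    return(structure(data.frame(birth = numeric(0), death = numeric(0),
                                tip = integer(0)), class = c("barcode",
                                                             "data.frame")))
  # champion (farthest tip, ties -> smaller node id) per subtree, leaf-up
  champ <- rep(NA_integer_, maxid)
  champ[tips] <- tips
  births <- numeric(0); deaths <- numeric(0); btips <- integer(0)
  for (v in rev(ord)) {
    ch <- kids[[as.character(v)]]
    if (is.null(ch) || !length(ch)) next
    cands <- champ[ch]
    dd <- gdist[cands]
    best <- order(-dd, cands)[1]
    champ[v] <- cands[best]
    if (length(ch) > 1) {
      for (k in seq_along(ch)[-best]) {
        births <- c(births, gdist[cands[k]])
        deaths <- c(deaths, gdist[v])
        btips <- c(btips, cands[k])
      }
    }
  }
  births <- c(births, gdist[champ[1L]])
  deaths <- c(deaths, 0)
  btips <- c(btips, champ[1L])
  o <- order(-births, deaths)
  structure(data.frame(birth = births[o], death = deaths[o], tip = btips[o]),
            class = c("barcode", "data.frame"))
}

#' Bottleneck distance between persistence barcodes
#'
#' The standard bottleneck distance: the minimum over partial matchings
#' (bars may be matched to the diagonal at half their persistence) of the
#' maximum matched sup-norm distance.  Solved by binary search over the
#' candidate radii with bipartite feasibility matching.
#'
#' @param b1,b2 \code{barcode} objects (or data frames with \code{birth}
#'   and \code{death})
#' @return the bottleneck distance (cm)
#' @export
bottleneck_distance <- function(b1, b2) {
  m1 <- cbind(b1$birth, b1$death); m2 <- cbind(b2$birth, b2$death)
  n1 <- nrow(m1); n2 <- nrow(m2)
  if (n1 == 0 && n2 == 0) return(0)
  diag1 <- if (n1) abs(m1[, 1] - m1[, 2]) / 2 else numeric(0)
  diag2 <- if (n2) abs(m2[, 1] - m2[, 2]) / 2 else numeric(0)
  if (n1 == 0) return(max(diag2))
  if (n2 == 0) return(max(diag1))
  cost <- outer(m1[, 1], m2[, 1], function(a, b) abs(a - b))
  cost <- pmax(cost, outer(m1[, 2], m2[, 2], function(a, b) abs(a - b)))
  cand <- sort(unique(c(0, cost, diag1, diag2)))
  feasible <- function(r) {
    # left: bars1 + shadow diagonal slots for bars2
    # right: bars2 + shadow diagonal slots for bars1
    edges <- integer(0)
    nl <- n1 + n2; nr <- n2 + n1
    add <- function(i, j) edges <<- c(edges, i, nl + j)
    for (i in seq_len(n1)) {
      for (j in seq_len(n2)) if (cost[i, j] <= r + 1e-12) add(i, j)
      if (diag1[i] <= r + 1e-12) add(i, n2 + i)
    }
    for (j in seq_len(n2)) if (diag2[j] <= r + 1e-12) add(n1 + j, j)
    for (j in seq_len(n2)) for (i in seq_len(n1)) add(n1 + j, n2 + i)
    g <- igraph::make_bipartite_graph(c(rep(FALSE, nl), rep(TRUE, nr)),
                                      edges)
    igraph::max_bipartite_match(g)$matching_size == nl
  }
  lo <- 1L; hi <- length(cand)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (feasible(cand[mid])) hi <- mid else lo <- mid + 1L
  }
  cand[lo]
}
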