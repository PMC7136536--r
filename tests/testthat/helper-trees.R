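# small hand-built root systems and brute-force oracles used across tests

# a straight tap root from the collar, n_nodes nodes, total length L
make_straight_root <- function(L = 10, n_nodes = 5) {
  z <- seq(0, -L, length.out = n_nodes)
  root_system(
    data.frame(id = seq_len(n_nodes), x = 0, y = 0, z = z,
               ctime = seq(0, 1, length.out = n_nodes), radius = 0.05),
    data.frame(prox = seq_len(n_nodes - 1), dist = 2:n_nodes,
               root_id = 1L, order = 0L))
}

# tap root of length l_tap with one lateral of length l_lat attached at
# distance d_branch from the collar
make_tap_with_lateral <- function(l_tap = 10, l_lat = 3, d_branch = 4) {
  nodes <- data.frame(
    id = 1:4,
    x = c(0, 0, 0, l_lat),
    y = 0,
    z = c(0, -d_branch, -l_tap, -d_branch),
    ctime = 0, radius = 0.05)
  segs <- data.frame(prox = c(1, 2, 2), dist = c(2, 3, 4),
                     root_id = c(1, 1, 2), order = c(0, 0, 1))
  roots <- data.frame(root_id = 1:2, parent_root = c(NA, 1L),
                      parent_node = c(1L, 2L), order = 0:1,
                      type = c("tap", "lateral1"))
  root_system(nodes, segs, roots)
}

# herringbone: tap root with k laterals at unit spacing
make_herringbone <- function(k = 4, l_lat = 1) {
  nodes <- data.frame(id = 1L, x = 0, y = 0, z = 0, ctime = 0,
                      radius = 0.05)
  segs <- data.frame(prox = integer(0), dist = integer(0),
                     root_id = integer(0), order = integer(0))
  nid <- 1L
  prev <- 1L
  branch_nodes <- integer(0)
  for (i in seq_len(k + 1)) {
    nid <- nid + 1L
    nodes <- rbind(nodes, data.frame(id = nid, x = 0, y = 0, z = -i,
                                     ctime = 0, radius = 0.05))
    segs <- rbind(segs, data.frame(prox = prev, dist = nid, root_id = 1L,
                                   order = 0L))
    if (i <= k) branch_nodes <- c(branch_nodes, nid)
    prev <- nid
  }
  rid <- 1L
  for (b in branch_nodes) {
    rid <- rid + 1L
    nid <- nid + 1L
    bz <- nodes$z[nodes$id == b]
    nodes <- rbind(nodes, data.frame(id = nid, x = l_lat, y = 0, z = bz,
                                     ctime = 0, radius = 0.05))
    segs <- rbind(segs, data.frame(prox = b, dist = nid, root_id = rid,
                                   order = 1L))
  }
  root_system(nodes, segs)
}

# perfect binary link-tree of the given depth on top of a trunk link
make_binary_tree <- function(depth = 3) {
  nodes <- data.frame(id = 1:2, x = c(0, 0), y = 0, z = c(0, -1),
                      ctime = 0, radius = 0.05)
  segs <- data.frame(prox = 1L, dist = 2L, root_id = 1L, order = 0L)
  env <- new.env()
  env$nid <- 2L; env$nodes <- nodes; env$segs <- segs; env$rid <- 1L
  rec <- function(par, d, x, spread) {
    if (d == 0) return()
    pz <- env$nodes$z[env$nodes$id == par]
    for (s in c(-1, 1)) {
      env$nid <- env$nid + 1L
      env$rid <- env$rid + 1L
      env$nodes <- rbind(env$nodes,
                         data.frame(id = env$nid, x = x + s * spread, y = 0,
                                    z = pz - 1, ctime = 0, radius = 0.05))
      env$segs <- rbind(env$segs,
                        data.frame(prox = par, dist = env$nid,
                                   root_id = env$rid, order = 1L))
      rec(env$nid, d - 1, x + s * spread, spread / 2)
    }
  }
  rec(2L, depth, 0, 4)
  root_system(env$nodes, env$segs)
}

# brute-force bottleneck distance by enumerating all partial matchings
# (feasible for barcodes with <= 6 bars)
brute_bottleneck <- function(b1, b2) {
  m1 <- cbind(b1$birth, b1$death); m2 <- cbind(b2$birth, b2$death)
  n1 <- nrow(m1); n2 <- nrow(m2)
  d1 <- if (n1) abs(m1[, 1] - m1[, 2]) / 2 else numeric(0)
  d2 <- if (n2) abs(m2[, 1] - m2[, 2]) / 2 else numeric(0)
  if (n1 == 0 && n2 == 0) return(0)
  if (n1 == 0) return(max(d2))
  if (n2 == 0) return(max(d1))
  pair_cost <- function(i, j)
    max(abs(m1[i, 1] - m2[j, 1]), abs(m1[i, 2] - m2[j, 2]))
  best <- Inf
  subsets <- function(v) {
    if (!length(v)) return(list(integer(0)))
    unlist(lapply(subsets(v[-1]), function(s) list(s, c(v[1], s))),
           recursive = FALSE)
  }
  for (S1 in subsets(seq_len(n1))) {       # bars of b1 sent to the diagonal
    keep1 <- setdiff(seq_len(n1), S1)
    for (S2 in subsets(seq_len(n2))) {
      keep2 <- setdiff(seq_len(n2), S2)
      if (length(keep1) != length(keep2)) next
      base <- max(c(0, d1[S1], d2[S2]))
      if (!length(keep1)) { best <- min(best, base); next }
      perms <- function(v) {
        if (length(v) <= 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
          for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
        out
      }
      for (p in perms(keep2)) {
        cc <- base
        for (k in seq_along(keep1))
          cc <- max(cc, pair_cost(keep1[k], p[k]))
        best <- min(best, cc)
      }
    }
  }
  best
}

# brute-force Fitter indices by explicit link-tree construction
brute_fitter <- function(rs) {
  sg <- rs$segments
  kids <- split(sg$dist, sg$prox)
  nk <- function(v) {
    k <- kids[[as.character(v)]]
    if (is.null(k)) integer(0) else k
  }
  tips <- setdiff(sg$dist, sg$prox)
  depth_of <- function(tip) {
    # count links along the path collar -> tip
    parent <- stats::setNames(sg$prox, sg$dist)
    path <- tip
    v <- tip
    while (v != 1L) { v <- parent[[as.character(v)]]; path <- c(v, path) }
    links <- 0
    for (i in seq_along(path)[-1]) {
      u <- path[i - 1]
      if (u == 1L || length(nk(u)) >= 2) links <- links + 1
    }
    links
  }
  dd <- vapply(tips, depth_of, numeric(1))
  list(magnitude = length(tips), altitude = max(dd),
       exterior_path_length = sum(dd))
}

random_barcode <- function(n, seed) {
  set.seed(seed)
  birth <- runif(n, 1, 10)
  death <- birth * runif(n, 0, 0.9)
  data.frame(birth = birth, death = death)
}
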