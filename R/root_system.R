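#' Root system data model
#'
#' A root system is a rooted tree of nodes (3D points with creation time and
#' radius) connected by segments, each segment belonging to a root (an
#' individual root axis).  The collar is node 1; the z axis points upward
#' with the soil surface at z = 0, so roots live at negative z.
#'
#' @param nodes data frame with columns \code{id}, \code{x}, \code{y},
#'   \code{z} (cm), \code{ctime} (d), \code{radius} (cm)
#' @param segments data frame with columns \code{prox}, \code{dist} (node
#'   ids), \code{root_id}, \code{order} (0 = tap/primary)
#' @param roots data frame with one row per root axis: \code{root_id},
#'   \code{parent_root}, \code{parent_node}, \code{order}, \code{type}
#' @return an object of class \code{root_system}
#' @export
root_system <- function(nodes, segments, roots = NULL) {
  if (is.null(roots)) {
    ids <- sort(unique(segments$root_id))
    roots <- data.frame(root_id = ids, parent_root = NA_integer_,
                        parent_node = NA_integer_,
                        order = segments$order[match(ids, segments$root_id)],
                        type = NA_character_)
  }
  rs <- structure(list(nodes = nodes, segments = segments, roots = roots),
                  class = "root_system")
  validate_root_system(rs)
  rs
}

#' Validate root-system tree invariants
#'
#' Checks that the structure is a connected rooted tree: every node except
#' the collar has exactly one incoming segment, there are no cycles, and all
#' segment lengths are positive.
#'
#' @param rs a \code{root_system}
#' @return the object, invisibly; errors otherwise
#' @export
validate_root_system <- function(rs) {
  nd <- rs$nodes; sg <- rs$segments
  stopifnot(all(c("id", "x", "y", "z", "ctime", "radius") %in% names(nd)),
            all(c("prox", "dist", "root_id", "order") %in% names(sg)))
  if (nrow(sg) == 0) return(invisible(rs))
  if (anyDuplicated(sg$dist))
    stop("node with more than one incoming segment: not a tree")
  if (any(sg$dist == 1L)) stop("collar node has an incoming segment")
  parent <- rep(NA_integer_, max(nd$id))
  parent[sg$dist] <- sg$prox
  depth <- rep(NA_integer_, max(nd$id))
  depth[1L] <- 0L
  for (v in nd$id) {
    chain <- integer(0); u <- v
    while (is.na(depth[u])) {
      chain <- c(chain, u)
      if (is.na(parent[u])) stop("node ", v, " not connected to the collar")
      u <- parent[u]
      if (length(chain) > nrow(nd)) stop("cycle detected in root system")
    }
    if (length(chain))
      depth[chain] <- depth[u] + rev(seq_along(chain))
  }
  len <- segment_lengths(rs)
  if (any(len <= 0)) stop("non-positive segment length")
  invisible(rs)
}

#' Segment lengths of a root system
#' @param rs a \code{root_system}
#' @return numeric vector (cm), one entry per segment row
#' @export
segment_lengths <- function(rs) {
  nd <- rs$nodes; sg <- rs$segments
  ix <- match(sg$prox, nd$id); jx <- match(sg$dist, nd$id)
  sqrt((nd$x[ix] - nd$x[jx])^2 + (nd$y[ix] - nd$y[jx])^2 +
         (nd$z[ix] - nd$z[jx])^2)
}

#' @export
print.root_system <- function(x, ...) {
  cat(sprintf(
    "<root_system> %d nodes, %d segments, %d roots, total length %.2f cm\n",
    nrow(x$nodes), nrow(x$segments), nrow(x$roots),
    sum(segment_lengths(x))))
  invisible(x)
}

#' Parameters of one root type for the stochastic growth model
#'
#' The growth rules are a deliberately minimal rule set of the
#' elongation/branching family used by stochastic root architecture
#' simulators: tips elongate with a negative-exponential approach to a
#' maximum length, laterals appear behind an unbranched apical zone at a
#' fixed inter-branch spacing after a delay, and tip directions combine the
#' previous direction, a gravitropic pull toward -z and a random Gaussian
#' deflection.
#'
#' @param r elongation rate (cm/d)
#' @param lmax maximum root length (cm); may be \code{Inf}
#' @param ln inter-branch distance (cm); \code{Inf} disables branching
#' @param la apical unbranched zone (cm)
#' @param lb basal unbranched zone (cm)
#' @param delay lateral emergence delay after the tip passes the site (d)
#' @param insertion_angle lateral insertion angle from the parent axis (rad)
#' @param tropism_strength gravitropic pull toward -z (per cm of growth)
#' @param tropism_sigma standard deviation of the random direction
#'   deflection (per sqrt(cm) of growth); 0 gives deterministic growth
#' @param radius root radius (cm)
#' @param lmax_cv coefficient of variation applied to \code{lmax} per root
#' @param successor type name of the laterals this type produces
#'   (\code{NA} for none)
#' @return a list of class \code{root_type}
#' @export
root_type <- function(r, lmax = Inf, ln = Inf, la = 1, lb = 0.5,
                      delay = 1, insertion_angle = 70 * pi / 180,
                      tropism_strength = 0.3, tropism_sigma = 0.2,
                      radius = 0.05, lmax_cv = 0, successor = NA_character_) {
  stopifnot(r >= 0, lmax > 0, la >= 0, lb >= 0, delay >= 0, radius > 0,
            lmax_cv >= 0)
  structure(list(r = r, lmax = lmax, ln = ln, la = la, lb = lb,
                 delay = delay, insertion_angle = insertion_angle,
                 tropism_strength = tropism_strength,
                 tropism_sigma = tropism_sigma, radius = radius,
                 lmax_cv = lmax_cv, successor = successor),
            class = "root_type")
}

#' Architecture parameter set
#'
#' @param types named list of \code{\link{root_type}} objects
#' @param first type of the primary axis
#' @param seed_position 3-vector (cm); the conventional benchmark seed
#'   position is (0, 0, -3)
#' @param dx spatial resolution of emitted segments (cm)
#' @return a list of class \code{architecture_params}
#' @export
architecture_params <- function(types, first = names(types)[1],
                                seed_position = c(0, 0, -3), dx = 0.25) {
  stopifnot(length(types) >= 1, first %in% names(types), dx > 0)
  structure(list(types = types, first = first,
                 seed_position = seed_position, dx = dx),
            class = "architecture_params")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Grow a stochastic root system
#'
#' Discrete-time growth under the rules of \code{\link{root_type}}.  The
#' target length of a root of age \eqn{a} is
#' \eqn{L(a) = l_{max}(1 - e^{-r a / l_{max}})}, so tips slow down as they
#' approach their maximum length and elongate at exactly \code{r} when
#' \code{lmax} is infinite.  Laterals emerge behind the apical zone at the
#' inter-branch spacing, delayed by the type's emergence delay, starting
#' from the parent node closest to the branching position.  Results are
#' reproducible for a fixed seed; the caller's RNG state is restored.
#'
#' @param params an \code{\link{architecture_params}}
#' @param t_sim simulated time (d)
#' @param dt growth time step (d)
#' @param seed RNG seed
#' @return a \code{root_system}
#' @export
grow_root_system <- function(params, t_sim, dt = 0.5, seed = 1L) {
  stopifnot(inherits(params, "architecture_params"), t_sim > 0, dt > 0)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  sp <- params$seed_position
  ty1 <- params$types[[params$first]]
  # growable node storage
  nx <- sp[1]; ny <- sp[2]; nz <- sp[3]; nct <- 0; nrad <- ty1$radius
  sprox <- integer(0); sdist <- integer(0); srid <- integer(0)
  sord <- integer(0)
  n_nodes <- 1L

  target_len <- function(lmax, r, age) {
    if (age <= 0) return(0)
    if (!is.finite(lmax)) r * age else lmax * (1 - exp(-r * age / lmax))
  }
  time_at_len <- function(lmax, r, l) {
    if (r <= 0) return(Inf)
    if (!is.finite(lmax)) l / r
    else if (l >= lmax) Inf
    else -lmax / r * log(1 - l / lmax)
  }
  sample_lmax <- function(ty) {
    if (ty$lmax_cv > 0 && is.finite(ty$lmax))
      max(2 * params$dx, ty$lmax * (1 + ty$lmax_cv * stats::rnorm(1)))
    else ty$lmax
  }
  rotate_insertion <- function(dir, angle) {
    a <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- cross3(dir, a); u <- u / sqrt(sum(u^2))
    w <- cross3(dir, u)
    phi <- stats::runif(1, 0, 2 * pi)
    d <- cos(angle) * dir + sin(angle) * (cos(phi) * u + sin(phi) * w)
    d / sqrt(sum(d^2))
  }

  # axes: list of mutable records; chain = node ids along the axis,
  # cumlen = distance from axis origin at each chain node
  axes <- list(list(type = params$first, t0 = 0, order = 0L,
                    parent_root = NA_integer_, origin_node = 1L,
                    chain = 1L, cumlen = 0, dir = c(0, 0, -1),
                    length = 0, lmax = sample_lmax(ty1),
                    next_branch = ty1$lb, pending = list()))

  t_now <- 0
  nsteps <- ceiling(t_sim / dt - 1e-9)
  for (step in seq_len(nsteps)) {
    t_new <- min(t_now + dt, t_sim)
    ri <- 1L
    while (ri <= length(axes)) {
      ax <- axes[[ri]]
      ty <- params$types[[ax$type]]
      Lt <- target_len(ax$lmax, ty$r, t_new - ax$t0)
      while (ax$length < Lt - 1e-9) {
        dl <- min(params$dx, Lt - ax$length)
        d <- ax$dir + ty$tropism_strength * dl * c(0, 0, -1)
        if (ty$tropism_sigma > 0)
          d <- d + ty$tropism_sigma * sqrt(dl) * stats::rnorm(3)
        d <- d / sqrt(sum(d^2))
        tipid <- ax$chain[length(ax$chain)]
        pnew <- c(nx[tipid], ny[tipid], nz[tipid]) + d * dl
        n_nodes <- n_nodes + 1L
        ct <- min(ax$t0 + time_at_len(ax$lmax, ty$r, ax$length + dl), t_new)
        nx[n_nodes] <- pnew[1]; ny[n_nodes] <- pnew[2]; nz[n_nodes] <- pnew[3]
        nct[n_nodes] <- ct; nrad[n_nodes] <- ty$radius
        sprox <- c(sprox, tipid); sdist <- c(sdist, n_nodes)
        srid <- c(srid, ri); sord <- c(sord, ax$order)
        ax$chain <- c(ax$chain, n_nodes)
        ax$length <- ax$length + dl
        ax$cumlen <- c(ax$cumlen, ax$length)
        ax$dir <- d
        if (!is.na(ty$successor) && is.finite(ty$ln)) {
          while (ax$length >= ax$next_branch + ty$la) {
            t_passed <- ax$t0 + time_at_len(ax$lmax, ty$r, ax$next_branch)
            ax$pending[[length(ax$pending) + 1L]] <-
              list(pos = ax$next_branch, t_emerge = t_passed + ty$delay)
            ax$next_branch <- ax$next_branch + ty$ln
          }
        }
      }
      # emerge matured laterals
      if (length(ax$pending)) {
        keep <- list()
        for (p in ax$pending) {
          if (p$t_emerge <= t_new) {
            k <- which.min(abs(ax$cumlen - p$pos))
            bnode <- ax$chain[k]
            # local parent direction at the branch node
            k2 <- min(k + 1L, length(ax$chain))
            k1 <- max(k2 - 1L, 1L)
            pd <- c(nx[ax$chain[k2]] - nx[ax$chain[k1]],
                    ny[ax$chain[k2]] - ny[ax$chain[k1]],
                    nz[ax$chain[k2]] - nz[ax$chain[k1]])
            if (sum(pd^2) < 1e-20) pd <- ax$dir
            pd <- pd / sqrt(sum(pd^2))
            sty_name <- ty$successor
            sty <- params$types[[sty_name]]
            if (is.null(sty)) stop("unknown successor type '", sty_name, "'")
            axes[[length(axes) + 1L]] <-
              list(type = sty_name, t0 = p$t_emerge, order = ax$order + 1L,
                   parent_root = ri, origin_node = bnode,
                   chain = bnode, cumlen = 0,
                   dir = rotate_insertion(pd, sty$insertion_angle),
                   length = 0, lmax = sample_lmax(sty),
                   next_branch = sty$lb, pending = list())
          } else keep[[length(keep) + 1L]] <- p
        }
        ax$pending <- keep
      }
      axes[[ri]] <- ax
      ri <- ri + 1L
    }
    t_now <- t_new
  }

  nodes <- data.frame(id = seq_len(n_nodes), x = nx, y = ny, z = nz,
                      ctime = nct, radius = nrad)
  segments <- data.frame(prox = sprox, dist = sdist, root_id = srid,
                         order = sord)
  roots <- data.frame(
    root_id = seq_along(axes),
    parent_root = vapply(axes, function(a) a$parent_root, integer(1)),
    parent_node = vapply(axes, function(a) a$origin_node, integer(1)),
    order = vapply(axes, function(a) a$order, integer(1)),
    type = vapply(axes, function(a) a$type, character(1)))
  # axes that never elongated leave no segments; drop them
  grown <- roots$root_id %in% unique(segments$root_id) | roots$order == 0L
  roots <- roots[grown, , drop = FALSE]
  root_system(nodes, segments, roots)
}

#' Split long segments
#'
#' Subdivides every segment longer than \code{max_seg_len} into equal parts
#' by linear interpolation of position, creation time and radius.  Total
#' length is preserved to machine precision and the tree topology is
#' unchanged apart from the inserted pass-through nodes.
#'
#' @param rs a \code{root_system}
#' @param max_seg_len maximum admissible segment length (cm)
#' @return a \code{root_system}
#' @export
discretize_root_system <- function(rs, max_seg_len) {
  stopifnot(max_seg_len > 0)
  nd <- rs$nodes; sg <- rs$segments
  len <- segment_lengths(rs)
  if (all(len <= max_seg_len)) return(rs)
  next_id <- max(nd$id) + 1L
  new_nodes <- list(nd)
  new_segs <- list()
  for (s in seq_len(nrow(sg))) {
    if (len[s] <= max_seg_len) {
      new_segs[[length(new_segs) + 1L]] <- sg[s, ]
      next
    }
    k <- ceiling(len[s] / max_seg_len)
    i <- match(sg$prox[s], nd$id); j <- match(sg$dist[s], nd$id)
    fr <- seq_len(k - 1) / k
    ids <- next_id + seq_len(k - 1) - 1L
    next_id <- next_id + k - 1L
    new_nodes[[length(new_nodes) + 1L]] <- data.frame(
      id = ids,
      x = nd$x[i] + fr * (nd$x[j] - nd$x[i]),
      y = nd$y[i] + fr * (nd$y[j] - nd$y[i]),
      z = nd$z[i] + fr * (nd$z[j] - nd$z[i]),
      ctime = nd$ctime[i] + fr * (nd$ctime[j] - nd$ctime[i]),
      radius = nd$radius[i] + fr * (nd$radius[j] - nd$radius[i]))
    chain <- c(sg$prox[s], ids, sg$dist[s])
    new_segs[[length(new_segs) + 1L]] <- data.frame(
      prox = chain[-length(chain)], dist = chain[-1],
      root_id = sg$root_id[s], order = sg$order[s])
  }
  root_system(do.call(rbind, new_nodes), do.call(rbind, new_segs), rs$roots)
}
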