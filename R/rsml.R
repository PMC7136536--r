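#' Write a root system to RSML
#'
#' Serializes the root system as Root System Markup Language: polylines
#' under nested \code{<root>} elements (laterals are children of their
#' parent's element), with per-node radius and creation time stored as
#' polyline-domain functions (\code{diameter}, \code{emergence_time}).
#' Numbers are written with fixed six-decimal formatting so that identical
#' root systems produce byte-identical files.
#'
#' @param rs a \code{root_system}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
write_rsml <- function(rs, path) {
  nd <- rs$nodes
  sg <- rs$segments
  fmt <- function(v) sprintf("%.6f", v)
  # chains per root: ordered node ids (origin first)
  chains <- rsml_chains(rs)
  children_of <- split(rs$roots$root_id, rs$roots$parent_root)

  root_xml <- function(rid) {
    ch <- chains[[as.character(rid)]]
    ix <- match(ch, nd$id)
    pts <- paste0(sprintf(
      '          <point x="%s" y="%s" z="%s"/>',
      fmt(nd$x[ix]), fmt(nd$y[ix]), fmt(nd$z[ix])), collapse = "\n")
    diam <- paste0(sprintf('          <sample value="%s"/>',
                           fmt(2 * nd$radius[ix])), collapse = "\n")
    emrg <- paste0(sprintf('          <sample value="%s"/>',
                           fmt(nd$ctime[ix])), collapse = "\n")
    kids <- children_of[[as.character(rid)]]
    kid_xml <- if (is.null(kids)) "" else
      paste0(vapply(kids, root_xml, character(1)), collapse = "")
    paste0(
      sprintf('      <root ID="%d" label="root_%d">\n', rid, rid),
      "        <geometry>\n        <polyline>\n", pts,
      "\n        </polyline>\n        </geometry>\n",
      "        <functions>\n",
      '        <function name="diameter" domain="polyline">\n', diam,
      "\n        </function>\n",
      '        <function name="emergence_time" domain="polyline">\n', emrg,
      "\n        </function>\n        </functions>\n",
      kid_xml,
      "      </root>\n")
  }
  top <- rs$roots$root_id[is.na(rs$roots$parent_root)]
  body <- paste0(vapply(top, root_xml, character(1)), collapse = "")
  txt <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    "<rsml>\n  <metadata>\n    <version>1</version>\n",
    "    <unit>cm</unit>\n    <resolution>1</resolution>\n",
    "    <software>rootbench</software>\n  </metadata>\n",
    '  <scene>\n    <plant id="1" label="plant">\n',
    body,
    "    </plant>\n  </scene>\n</rsml>\n")
  writeLines(txt, path, sep = "")
  invisible(path)
}

# ordered node chain for every root axis (origin node first).
rsml_chains <- function(rs) {
  sg <- rs$segments
  out <- list()
  for (rid in rs$roots$root_id) {
    s <- sg[sg$root_id == rid, , drop = FALSE]
    if (nrow(s) == 0) next
    starts <- setdiff(s$prox, s$dist)
    if (length(starts) != 1)
      stop("root ", rid, " is not a simple chain")
    chain <- starts
    nxt <- s$dist[match(chain[length(chain)], s$prox)]
    while (!is.na(nxt)) {
      chain <- c(chain, nxt)
      nxt <- s$dist[match(nxt, s$prox)]
    }
    out[[as.character(rid)]] <- chain
  }
  out
}

#' Read a root system from RSML
#'
#' Parses the scene/plant/root hierarchy with polyline geometry; nested
#' \code{<root>} elements become lateral roots attached at the parent node
#' closest to their first polyline point (exactly coincident points are
#' merged).  Branching order is recomputed from nesting depth.  The
#' \code{diameter} and \code{emergence_time} polyline functions fill radius
#' and creation time when present; unknown extensions are ignored.
#'
#' @param path RSML file path
#' @return a \code{root_system}
#' @export
read_rsml <- function(path) {
  doc <- xml2::read_xml(path)
  plants <- xml2::xml_find_all(doc, ".//scene/plant")
  if (length(plants) == 0) stop("RSML: no <plant> under <scene> in ", path)
  env <- new.env()
  env$nx <- numeric(0); env$ny <- numeric(0); env$nz <- numeric(0)
  env$nct <- numeric(0); env$nrad <- numeric(0)
  env$prox <- integer(0); env$dist <- integer(0)
  env$srid <- integer(0); env$sord <- integer(0)
  env$rid <- 0L
  env$roots <- list()

  add_node <- function(p, ct, rad) {
    k <- length(env$nx) + 1L
    env$nx[k] <- p[1]; env$ny[k] <- p[2]; env$nz[k] <- p[3]
    env$nct[k] <- ct; env$nrad[k] <- rad
    k
  }

  parse_root <- function(el, order, parent_root, attach_node) {
    poly <- xml2::xml_find_first(el, "./geometry/polyline")
    if (inherits(poly, "xml_missing"))
      stop("RSML: root element without polyline geometry (",
           xml2::xml_path(el), ")")
    pts <- xml2::xml_find_all(poly, "./point")
    if (length(pts) < 1)
      stop("RSML: empty polyline (", xml2::xml_path(el), ")")
    gx <- as.numeric(xml2::xml_attr(pts, "x"))
    gy <- as.numeric(xml2::xml_attr(pts, "y"))
    gz <- as.numeric(xml2::xml_attr(pts, "z"))
    gz[is.na(gz)] <- 0
    fn_vals <- function(name) {
      f <- xml2::xml_find_first(el, sprintf(
        "./functions/function[@name='%s']", name))
      if (inherits(f, "xml_missing")) return(NULL)
      as.numeric(xml2::xml_attr(xml2::xml_find_all(f, "./sample"), "value"))
    }
    diam <- fn_vals("diameter")
    emrg <- fn_vals("emergence_time")
    rad <- if (!is.null(diam) && length(diam) == length(pts)) diam / 2
           else rep(0.05, length(pts))
    ct <- if (!is.null(emrg) && length(emrg) == length(pts)) emrg
          else rep(0, length(pts))
    env$rid <- env$rid + 1L
    rid <- env$rid
    # attach: if the first point coincides with the attach node, reuse it
    first_k <- 1L
    prev <- attach_node
    if (!is.null(attach_node)) {
      d0 <- sqrt((env$nx[attach_node] - gx[1])^2 +
                   (env$ny[attach_node] - gy[1])^2 +
                   (env$nz[attach_node] - gz[1])^2)
      if (d0 < 1e-6) first_k <- 2L
    } else {
      prev <- add_node(c(gx[1], gy[1], gz[1]), ct[1], rad[1])
      first_k <- 2L
    }
    if (first_k <= length(pts)) {
      for (k in first_k:length(pts)) {
        cur <- add_node(c(gx[k], gy[k], gz[k]), ct[k], rad[k])
        env$prox <- c(env$prox, prev); env$dist <- c(env$dist, cur)
        env$srid <- c(env$srid, rid); env$sord <- c(env$sord, order)
        prev <- cur
      }
    }
    env$roots[[rid]] <- data.frame(
      root_id = rid,
      parent_root = if (is.null(parent_root)) NA_integer_ else parent_root,
      parent_node = if (is.null(attach_node)) NA_integer_ else attach_node,
      order = order,
      type = if (order == 0L) "tap" else paste0("lateral", order))
    # children attach at the parent node nearest their first point
    this_chain_first <- if (is.null(attach_node)) 1L else attach_node
    kids <- xml2::xml_find_all(el, "./root")
    for (kid in kids) {
      kpt <- xml2::xml_find_first(kid, "./geometry/polyline/point")
      kp <- c(as.numeric(xml2::xml_attr(kpt, "x")),
              as.numeric(xml2::xml_attr(kpt, "y")),
              as.numeric(xml2::xml_attr(kpt, "z")))
      if (is.na(kp[3])) kp[3] <- 0
      own <- which(env$srid == rid)
      cand <- unique(c(this_chain_first, env$dist[own]))
      dd <- sqrt((env$nx[cand] - kp[1])^2 + (env$ny[cand] - kp[2])^2 +
                   (env$nz[cand] - kp[3])^2)
      parse_root(kid, order + 1L, rid, cand[which.min(dd)])
    }
    rid
  }

  collar <- NULL
  for (pl in plants) {
    for (r in xml2::xml_find_all(pl, "./root")) {
      parse_root(r, 0L, NULL, collar)
      # additional top-level axes are joined at the first root's origin
      if (is.null(collar)) collar <- 1L
    }
  }
  nodes <- data.frame(id = seq_along(env$nx), x = env$nx, y = env$ny,
                      z = env$nz, ctime = env$nct, radius = env$nrad)
  segments <- data.frame(prox = env$prox, dist = env$dist,
                         root_id = env$srid, order = env$sord)
  roots <- do.call(rbind, env$roots)
  root_system(nodes, segments, roots)
}
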