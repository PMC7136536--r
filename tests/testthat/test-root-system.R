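test_that("deterministic growth: length equals rate times time", {
  p <- architecture_params(list(
    tap = root_type(r = 2, tropism_strength = 0, tropism_sigma = 0)))
  rs <- grow_root_system(p, 5, dt = 0.5, seed = 1)
  expect_equal(sum(segment_lengths(rs)), 10, tolerance = 1e-9)
  # straight down from the seed at (0,0,-3)
  expect_equal(min(rs$nodes$z), -13, tolerance = 1e-9)
  expect_equal(rs$nodes$x, rep(0, nrow(rs$nodes)))
})

test_that("zero elongation gives an empty (seed-only) system", {
  p <- architecture_params(list(tap = root_type(r = 0)))
  rs <- grow_root_system(p, 5, seed = 1)
  expect_equal(nrow(rs$segments), 0)
  expect_equal(nrow(rs$nodes), 1)
})

test_that("negative-exponential slowdown approaches lmax", {
  p <- architecture_params(list(
    tap = root_type(r = 2, lmax = 10, tropism_strength = 0,
                    tropism_sigma = 0)))
  rs <- grow_root_system(p, 5, dt = 0.25, seed = 1)
  expect_equal(sum(segment_lengths(rs)), 10 * (1 - exp(-1)),
               tolerance = 1e-6)
  rs2 <- grow_root_system(p, 60, dt = 0.25, seed = 1)
  expect_lt(sum(segment_lengths(rs2)), 10 + 1e-9)
})

test_that("growth is reproducible for a seed and differs across seeds", {
  p <- fixture_params("lupine")
  a <- grow_root_system(p, 10, seed = 42)
  b <- grow_root_system(p, 10, seed = 42)
  c <- grow_root_system(p, 10, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$nodes, c$nodes))
  # growing does not perturb the caller's RNG stream
  set.seed(5); x1 <- runif(1)
  set.seed(5); invisible(grow_root_system(p, 3, seed = 1)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("grown systems keep tree invariants and the length budget", {
  p <- fixture_params("lupine")
  for (seed in 1:3) {
    rs <- grow_root_system(p, 12, dt = 0.5, seed = seed)
    expect_silent(validate_root_system(rs))
    # laterals exist and carry increasing order
    expect_setequal(unique(rs$segments$order), c(0L, 1L))
    # total length cannot exceed the sum of unconstrained tip budgets
    nlat <- sum(rs$roots$order == 1)
    tap <- p$types$tap; lat <- p$types$lateral1
    expect_lt(sum(segment_lengths(rs)),
              tap$r * 12 + nlat * lat$r * 12 + 1e-9)
  }
})

test_that("RSML round-trips structurally and byte-identically", {
  rs <- grow_root_system(fixture_params("lupine"), 12, seed = 7)
  f1 <- tempfile(fileext = ".rsml"); f2 <- tempfile(fileext = ".rsml")
  write_rsml(rs, f1)
  ra <- read_rsml(f1)
  write_rsml(ra, f2)
  expect_identical(readLines(f1), readLines(f2))
  # geometry preserved to 1e-6 cm, topology exactly
  expect_equal(nrow(ra$segments), nrow(rs$segments))
  expect_equal(nrow(ra$roots), nrow(rs$roots))
  expect_lt(abs(sum(segment_lengths(ra)) - sum(segment_lengths(rs))), 1e-4)
  expect_equal(sort(ra$roots$order), sort(rs$roots$order))
  # per-node attributes carried through the polyline functions
  expect_equal(sort(unique(round(ra$nodes$radius, 6))),
               sort(unique(round(rs$nodes$radius, 6))))
})

test_that("RSML: a 3-root fixture nests two laterals under the tap", {
  rs <- make_tap_with_lateral()
  # add a second lateral at the same branch node
  nodes <- rbind(rs$nodes,
                 data.frame(id = 5L, x = -2, y = 0, z = -4, ctime = 0,
                            radius = 0.05))
  segs <- rbind(rs$segments,
                data.frame(prox = 2L, dist = 5L, root_id = 3L, order = 1L))
  roots <- rbind(rs$roots,
                 data.frame(root_id = 3L, parent_root = 1L,
                            parent_node = 2L, order = 1L,
                            type = "lateral1"))
  rs3 <- root_system(nodes, segs, roots)
  f <- tempfile(fileext = ".rsml")
  write_rsml(rs3, f)
  doc <- xml2::read_xml(f)
  top <- xml2::xml_find_all(doc, "./scene/plant/root")
  expect_length(top, 1)
  expect_length(xml2::xml_find_all(top, "./root"), 2)
  rt <- read_rsml(f)
  expect_equal(nrow(rt$roots), 3)
  expect_equal(sum(rt$roots$order == 1), 2)
})

test_that("a single polyline of N points reads as N-1 segments", {
  f <- tempfile(fileext = ".rsml")
  pts <- paste(sprintf('<point x="%d" y="0" z="%d"/>', 0:4 * 0, -(0:4)),
               collapse = "")
  writeLines(sprintf(
    '<?xml version="1.0"?><rsml><scene><plant>
     <root ID="1"><geometry><polyline>%s</polyline></geometry></root>
     </plant></scene></rsml>', pts), f)
  rs <- read_rsml(f)
  expect_equal(nrow(rs$segments), 4)
  expect_equal(sum(segment_lengths(rs)), 4)
  expect_error(read_rsml(textConnection("<rsml><scene/></rsml>")), "plant")
})

test_that("discretize splits long segments and preserves length", {
  rs <- make_straight_root(L = 10, n_nodes = 2)   # one 10 cm segment
  r2 <- discretize_root_system(rs, 0.5)
  expect_equal(nrow(r2$segments), 20)
  expect_equal(sum(segment_lengths(r2)), 10, tolerance = 1e-9)
  expect_lte(max(segment_lengths(r2)), 0.5 + 1e-12)
  # identity when nothing exceeds the limit
  expect_identical(discretize_root_system(r2, 1), r2)
  # arbitrary tree: count grows, length invariant, tree stays valid
  rs3 <- grow_root_system(fixture_params("lupine"), 10, seed = 3)
  r3 <- discretize_root_system(rs3, 0.1)
  expect_gt(nrow(r3$segments), nrow(rs3$segments))
  expect_equal(sum(segment_lengths(r3)), sum(segment_lengths(rs3)),
               tolerance = 1e-9)
  expect_silent(validate_root_system(r3))
})

test_that("tree invariant violations are detected", {
  nd <- data.frame(id = 1:3, x = 0, y = 0, z = c(0, -1, -2), ctime = 0,
                   radius = 0.05)
  # two incoming segments at one node
  expect_error(root_system(nd, data.frame(prox = c(1, 1), dist = c(2, 2),
                                          root_id = 1L, order = 0L)),
               "more than one")
  # disconnected node
  expect_error(root_system(nd, data.frame(prox = 2, dist = 3,
                                          root_id = 1L, order = 0L)),
               "not connected")
})
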