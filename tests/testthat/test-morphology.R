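test_that("default morphology matches the documented geometry", {
  m <- build_simplified_pyramidal()
  s <- m$sections
  expect_equal(s$L[s$name == "trunk_prox"], 100)
  expect_equal(s$L[s$name == "trunk_dist"], 400)
  expect_equal(s$nseg[s$name == "trunk_prox"], 19L)
  expect_equal(s$nseg[s$name == "trunk_dist"], 73L)
  # apical trunk totals 500 um
  expect_equal(s$L[s$name == "trunk_prox"] + s$L[s$name == "trunk_dist"], 500)
  # first-order branches carry 2/3 of the mother diameter
  expect_equal(s$diam[s$name == "oblique"], 2 * 2 / 3)
  expect_equal(s$diam[s$name == "tuft_a"], 2 * 2 / 3)
  expect_equal(s$diam[s$name == "basal_a"], 1 * 2 / 3)
  # soma is the unique root; the axon attaches to the soma
  expect_equal(sum(is.na(s$parent)), 1L)
  expect_identical(s$name[is.na(s$parent)], "soma")
  expect_identical(s$parent[s$name == "axon"], "soma")
  # empty overrides are the identity
  expect_identical(build_simplified_pyramidal(list())$sections, s)
})

test_that("morphology rejects unknown and degenerate parameters", {
  expect_error(build_simplified_pyramidal(list(nope = 1)), "unknown")
  expect_error(build_simplified_pyramidal(list(trunk_diam = -1)),
               "non-positive")
})

test_that("segment areas follow the cylinder formula", {
  m <- build_simplified_pyramidal()
  expect_equal(m$segs$area_cm2,
               pi * (m$segs$diam_um * 1e-4) * (m$segs$L_um * 1e-4))
})

test_that("path distances resolve the documented landmarks", {
  m <- build_simplified_pyramidal()
  # oblique junction is 100 um from the soma
  expect_equal(path_distance(m, site("soma", 0.5), site("trunk_prox", 1)), 100)
  expect_equal(path_distance(m, site_um(90, "apical"), site_um(90, "apical")), 0)
  # a point and itself anywhere
  expect_equal(path_distance(m, site("oblique", 0.3), site("oblique", 0.3)), 0)
  # triangle equality along a single path: soma -> 90 um -> junction
  a <- site("soma", 0.5); b <- site_um(90, "apical"); cc <- site("trunk_prox", 1)
  expect_equal(path_distance(m, a, cc),
               path_distance(m, a, b) + path_distance(m, b, cc))
  expect_error(resolve_site(m, site("nonexistent", 0.5)), "unknown section")
})

test_that("path distance agrees with a graph-traversal oracle", {
  skip_if_not_installed("igraph")
  m <- build_simplified_pyramidal()
  s <- m$sections
  # independent oracle: graph over section endpoints, edge weight = length;
  # soma collapses to a single node (point in the path metric)
  node <- function(sec, end) if (sec == "soma") "soma" else paste(sec, end)
  edges <- character(0); w <- numeric(0)
  for (i in seq_len(nrow(s))) {
    if (s$name[i] == "soma") next
    edges <- c(edges, node(s$name[i], 0), node(s$name[i], 1))
    w <- c(w, s$L[i])
    par <- s$parent[i]
    pnode <- if (par == "soma") "soma" else node(par, s$parent_x[i])
    edges <- c(edges, node(s$name[i], 0), pnode)
    w <- c(w, 0)
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  igraph::E(g)$weight <- w
  set.seed(42)
  secs <- setdiff(s$name, "soma")
  for (k in 1:25) {
    s1 <- sample(secs, 1); s2 <- sample(secs, 1)
    # oracle distance between the 1-ends via shortest path, then adjust to
    # interior points using the distance to each section's 0-end
    x1 <- stats::runif(1); x2 <- stats::runif(1)
    L1 <- s$L[s$name == s1]; L2 <- s$L[s$name == s2]
    d00 <- igraph::distances(g, node(s1, 0), node(s2, 0))[1, 1]
    d01 <- igraph::distances(g, node(s1, 0), node(s2, 1))[1, 1]
    d10 <- igraph::distances(g, node(s1, 1), node(s2, 0))[1, 1]
    d11 <- igraph::distances(g, node(s1, 1), node(s2, 1))[1, 1]
    oracle <- if (s1 == s2) abs(x1 - x2) * L1 else
      min(d00 + x1 * L1 + x2 * L2,
          d01 + x1 * L1 + (1 - x2) * L2,
          d10 + (1 - x1) * L1 + x2 * L2,
          d11 + (1 - x1) * L1 + (1 - x2) * L2)
    expect_equal(path_distance(m, site(s1, x1), site(s2, x2)), oracle,
                 tolerance = 1e-9)
  }
})

test_that("SWC export is standard and round-trips the tree metric", {
  m <- build_simplified_pyramidal()
  lines <- export_swc(m)
  rows <- read.table(text = lines[!startsWith(lines, "#")],
                     col.names = c("id", "type", "x", "y", "z", "r", "parent"))
  # radii are half the section diameters
  expect_equal(sort(unique(round(rows$r * 2, 4))),
               sort(unique(round(m$sections$diam, 4))))
  # exactly one root, of soma type
  expect_equal(sum(rows$parent == -1), 1)
  expect_equal(rows$type[rows$parent == -1], 1)

  m2 <- read_swc(lines)
  # section lengths survive within 0.1 um
  orig <- m$sections$L[-1]   # non-root, in sample order
  back <- m2$sections$L[-1]
  expect_true(all(abs(sort(orig) - sort(back)) < 0.1))
  # path-distance matrix over section endpoints is preserved
  ids <- seq_len(nrow(m$sections))[-1]
  for (i in c(2, 5, 9, 12)) for (j in c(3, 7, 14)) {
    n1 <- m$sections$name[i]; n2 <- m$sections$name[j]
    k1 <- paste0(c(soma = "soma", axon = "axon", basal = "basal",
                   trunk = "apical", oblique = "apical",
                   tuft = "apical")[m$sections$kind[i]], "_", i)
    k2 <- paste0(c(soma = "soma", axon = "axon", basal = "basal",
                   trunk = "apical", oblique = "apical",
                   tuft = "apical")[m$sections$kind[j]], "_", j)
    expect_equal(path_distance(m, site(n1, 1), site(n2, 1)),
                 path_distance(m2, site(k1, 1), site(k2, 1)),
                 tolerance = 0.1)
  }
})
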