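test_that("nd follows the (d-1)/(dmax-1) scale on a pectinate ladder", {
  lad <- ape::read.tree(text = "(a,(b,(c,(d,e))));")
  nd <- node_distance(lad)
  expect_equal(setNames(nd$nd, nd$label),
               c(a = 0, b = 1 / 3, c = 2 / 3, d = 1, e = 1))
})

test_that("a star tree scores every leaf at nd 0", {
  star <- ape::read.tree(text = "(a,b,c,d);")
  nd <- node_distance(star, assume_rooted = TRUE)
  expect_equal(nd$nd, rep(0, 4))
})

test_that("nd endpoints are 0 and 1 on any non-degenerate rooted tree", {
  set.seed(61)
  for (i in 1:30) {
    tr <- ape::rtree(sample(4:20, 1))
    nd <- node_distance(tr)
    expect_equal(min(nd$nd), 0)
    expect_equal(max(nd$nd), 1)
    expect_true(all(nd$nd >= 0 & nd$nd <= 1))
  }
  expect_error(node_distance(ape::unroot(ape::rtree(6))), "rooted")
})

test_that("nd is invariant to ladderization and rotation", {
  set.seed(62)
  tr <- ape::rtree(10)
  nd1 <- node_distance(tr)
  tr2 <- ape::rotateConstr(tr, rev(tr$tip.label))
  nd2 <- node_distance(tr2)
  expect_equal(nd1$nd[match(nd2$label, nd1$label)], nd2$nd)
  lad <- ape::ladderize(tr)
  nd3 <- node_distance(lad)
  expect_equal(nd1$nd[match(nd3$label, nd1$label)], nd3$nd)
})

test_that("collapsing a node can only reduce depths, nd stays in [0,1]", {
  set.seed(63)
  tr <- ape::rtree(12)
  nd1 <- node_distance(tr)
  coll <- ape::di2multi(tr, tol = max(tr$edge.length) * 0.5)
  attr(coll, "rooted") <- TRUE
  nd2 <- node_distance(coll)
  m <- match(nd2$label, nd1$label)
  expect_true(all(nd2$depth <= nd1$depth[m]))
  expect_true(all(nd2$nd >= 0 & nd2$nd <= 1))
})

test_that("cumulative accretion matches a direct sort-and-count oracle", {
  lad <- ape::read.tree(text = "(a,(b,(c,(d,e))));")
  amap <- node_distance(lad)
  acc <- cumulative_accretion(amap)
  expect_equal(acc$nd, sort(unique(amap$nd)))
  expect_true(all(diff(acc$cum_count) >= 0))
  expect_equal(max(acc$cum_count), 5L)
  expect_equal(acc$cum_frac[nrow(acc)], 1)
  # oracle: counts by sorting
  for (k in seq_len(nrow(acc))) {
    expect_equal(acc$cum_count[k], sum(amap$nd <= acc$nd[k] + 1e-12))
  }
  # grouped version
  groups <- setNames(c("x", "x", "y", "y", "y"), c("a", "b", "c", "d", "e"))
  accg <- cumulative_accretion(amap, groups)
  expect_equal(max(accg$cum_count[accg$group == "x"]), 2L)
  expect_equal(max(accg$cum_count[accg$group == "y"]), 3L)
})

test_that("heat maps colour scored elements and grey out unscored ones", {
  amap <- structure(
    tibble::tibble(label = c("P1", "P2"), depth = c(1L, 2L),
                   nd = c(0, 1), bin = c(1, 10)),
    class = c("ancestry_map", "tbl_df", "tbl", "data.frame"), bins = 10
  )
  layout <- data.frame(label = c("P1", "P2"),
                       x = c(40, 100), y = c(40, 40), shape = "rect")
  svg <- render_heatmap(amap, layout)
  expect_match(svg, "^<svg")
  f1 <- regmatches(svg, gregexpr('id="P[12]" [^>]*fill="[^"]*"', svg))[[1]]
  fills <- sub('.*fill="([^"]*)".*', "\\1", f1)
  expect_equal(length(unique(fills)), 2L)  # two distinct hues
  expect_match(svg, "<rect")               # legend present
  expect_match(svg, "0.9")                 # a bin boundary label

  layout2 <- rbind(layout,
                   data.frame(label = "P9", x = 160, y = 40, shape = "circle"))
  expect_warning(svg2 <- render_heatmap(amap, layout2), "P9")
  expect_match(svg2, 'id="P9"[^>]*fill="#bbbbbb"')
})

test_that("bin boundaries split [0,1] evenly", {
  nd <- seq(0, 1, by = 0.05)
  bins <- rnaclad:::nd_bin(nd, 10)
  expect_equal(min(bins), 1)
  expect_equal(max(bins), 10)
  expect_equal(rnaclad:::nd_bin(c(0.05, 0.15, 0.95), 10), c(1, 2, 10))
})

test_that("an SVG template is recoloured by element id", {
  tpl <- withr::local_tempfile(fileext = ".svg")
  writeLines(paste0(
    '<svg xmlns="http://www.w3.org/2000/svg">',
    '<rect id="P1" x="0" y="0" width="10" height="10" fill="none"/>',
    '<circle id="P2" cx="30" cy="5" r="4" fill="none"/></svg>'
  ), tpl)
  amap <- structure(
    tibble::tibble(label = c("P1", "P2"), depth = c(1L, 3L),
                   nd = c(0, 1), bin = c(1, 10)),
    class = c("ancestry_map", "tbl_df", "tbl", "data.frame"), bins = 10
  )
  out <- render_heatmap(amap, tpl)
  expect_false(grepl('fill="none"', out))
  expect_match(out, 'id="P1"')
})

test_that("autoplot methods return ggplot objects", {
  lad <- ape::read.tree(text = "(a,(b,(c,(d,e))));")
  amap <- node_distance(lad)
  expect_s3_class(autoplot(amap), "ggplot")
  expect_s3_class(autoplot(cumulative_accretion(amap)), "ggplot")
  set.seed(70)
  M <- random_matrix(4, 4, kind = rep("stabilizing", 4))
  expect_s3_class(autoplot(M), "ggplot")
})
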