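test_that("decomposition classifies the canonical toy cases", {
  d1 <- decompose_structure(
    parse_structure("((((....))))", "dotbracket", sequence = "GGGGAAAACCCC")
  )
  expect_equal(d1$kind, c("stem", "hairpin"))
  expect_equal(d1$length, c(4L, 4L))
  expect_false(any(d1$kind == "free_end"))

  d2 <- decompose_structure(parse_structure("..((..((...))..)).."))
  expect_equal(d2$kind, c("free_end", "stem", "internal_loop", "stem",
                          "hairpin", "free_end"))
  expect_equal(d2$length, c(2L, 2L, 4L, 2L, 3L, 2L))

  # one bulge side empty
  d3 <- decompose_structure(parse_structure("((..((...))))"))
  expect_equal(sort(unique(d3$kind)), c("bulge", "hairpin", "stem"))
  expect_equal(d3$length[d3$kind == "bulge"], 2L)
})

test_that("G:U pairs are counted per stem", {
  # pairs: G:U, U:G, G:C
  ss <- parse_structure("(((...)))", "dotbracket", sequence = "GUGAAACGU")
  d <- decompose_structure(ss)
  expect_equal(d$gu_count[d$kind == "stem"], 2L)
  expect_equal(d$gu_count[d$kind != "stem"], 0L)
})

test_that("multiloop segments and joints are recognized", {
  d <- decompose_structure(parse_structure("((.((...)).((...)).))"))
  expect_equal(sum(d$kind == "multiloop_segment"), 3L)
  d2 <- decompose_structure(parse_structure("((...))..((...))"))
  expect_equal(sum(d2$kind == "joint"), 1L)
  expect_equal(sum(d2$kind == "free_end"), 0L)
})

test_that("substructure spans partition every random molecule", {
  for (seed in 1:25) {
    ss <- random_structure(seed)
    d <- decompose_structure(ss)
    covered <- sort(unlist(lapply(d$span, function(sp) {
      unlist(lapply(seq_len(nrow(sp)), function(k) sp[k, 1]:sp[k, 2]))
    })))
    expect_equal(covered, 0:(nchar(ss$sequence) - 1L))
    # deterministic and idempotent
    expect_identical(d, decompose_structure(ss))
  }
})

test_that("labeling assigns canonical labels and emits absent ones at 0", {
  lab <- label_substructures(decompose_structure(toy_molecule()),
                             toy_scheme(), toy_annotation())
  expect_equal(lab$length[lab$label == "P1"], 4L)
  expect_equal(lab$length[lab$label == "P2"], 3L)
  expect_equal(lab$length[lab$label == "L1"], 3L)
  expect_equal(lab$length[lab$label == "L2"], 4L)
  expect_equal(lab$length[lab$label == "J1"], 2L)

  # a label with no matching interval is present with length 0
  scheme6 <- homology_scheme(c(toy_scheme()$label, "P6"),
                             c(toy_scheme()$kind, "stem"))
  lab6 <- label_substructures(decompose_structure(toy_molecule()),
                              scheme6, toy_annotation())
  expect_equal(lab6$length[lab6$label == "P6"], 0L)
})

test_that("labeling errors on unknown labels and kind mismatches", {
  d <- decompose_structure(toy_molecule())
  ann_bad <- toy_annotation()
  ann_bad$label[1] <- "P99"
  expect_error(label_substructures(d, toy_scheme(), ann_bad), "universe")

  # annotate the hairpin with a stem label -> kind mismatch
  ann_mis <- tibble::tibble(molecule_id = "toy", start = 5L, end = 7L,
                            label = "P2")
  expect_error(label_substructures(d, toy_scheme(), ann_mis), "kind")
})

test_that("coaxial tracts merge stems annotated with one composite label", {
  ss <- parse_structure("((((..((...))..))))", "dotbracket")
  d <- decompose_structure(ss)
  expect_equal(sum(d$kind == "stem"), 2L)
  scheme <- homology_scheme(c("P10-11", "L1"), c("stem", "hairpin"))
  ann <- tibble::tibble(
    molecule_id = "molecule",
    start = c(1L, 14L, 9L), end = c(8L, 19L, 11L),
    label = c("P10-11", "P10-11", "L1")
  )
  lab <- label_substructures(d, scheme, ann)
  expect_equal(lab$length[lab$label == "P10-11"], 6L)  # 4 + 2 bp
})
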