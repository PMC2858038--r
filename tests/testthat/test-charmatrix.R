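test_that("alphanumeric state codec follows the 0-9 A-Z a-z convention", {
  expect_equal(encode_state(c(0, 9)), c("0", "9"))
  expect_equal(encode_state(c(10, 35)), c("A", "Z"))
  expect_equal(encode_state(c(36, 61)), c("a", "z"))
  expect_warning(z <- encode_state(75), "clamped")
  expect_equal(z, "z")
  expect_error(encode_state(-1), "non-negative")
  expect_equal(decode_state(encode_state(0:61)), 0:61)
  expect_true(is.na(decode_state("?")))
  expect_error(decode_state("!"), "unknown")
})

test_that("matrix building codes lengths and zeros for missing labels", {
  lab <- label_substructures(decompose_structure(toy_molecule()),
                             toy_scheme(), toy_annotation())
  scheme6 <- homology_scheme(c(toy_scheme()$label, "P6"),
                             c(toy_scheme()$kind, "stem"))
  lab6 <- label_substructures(decompose_structure(toy_molecule()),
                              scheme6, toy_annotation())
  M <- build_char_matrix(lab6, scheme6)
  expect_equal(dim(M), c(1L, 6L))
  expect_equal(unname(M$states[1, "P6.len"]), 0L)
  expect_equal(unname(M$states[1, "P1.len"]), 4L)
  expect_equal(M$chars$kind[M$chars$char_id == "P1.len"], "stabilizing")
  expect_equal(M$chars$kind[M$chars$char_id == "L1.len"], "destabilizing")

  # two identical molecules -> two identical rows
  m2 <- toy_molecule(); m2$molecule_id <- "toy2"
  d2 <- decompose_structure(m2)
  ann2 <- toy_annotation(); ann2$molecule_id <- "toy2"
  lab2 <- label_substructures(d2, toy_scheme(), ann2)
  both <- build_char_matrix(dplyr::bind_rows(lab, lab2), toy_scheme())
  expect_equal(unname(both$states[1, ]), unname(both$states[2, ]))
})

test_that("gu characters are emitted only on request", {
  ss <- parse_structure("(((...)))", "dotbracket", sequence = "GUGAAACGU")
  scheme <- homology_scheme(c("P1", "L1"), c("stem", "hairpin"))
  ann <- tibble::tibble(molecule_id = "molecule",
                        start = c(1L, 7L, 4L), end = c(3L, 9L, 6L),
                        label = c("P1", "P1", "L1"))
  lab <- label_substructures(decompose_structure(ss), scheme, ann)
  expect_false("P1.gu" %in% build_char_matrix(lab, scheme)$chars$char_id)
  Mg <- build_char_matrix(lab, scheme, gu = TRUE)
  expect_equal(unname(Mg$states[1, "P1.gu"]), 2L)
  expect_equal(Mg$chars$kind[Mg$chars$char_id == "P1.gu"], "stabilizing")
})

test_that("the polarized ancestor takes column maxima for stems, 0 for loops", {
  st <- rbind(a = c(3L, 0L), b = c(7L, 4L), c = c(12L, 9L))
  M <- char_matrix(st, tibble::tibble(
    char_id = c("P1.len", "L1.len"),
    kind = c("stabilizing", "destabilizing"),
    domain = "none", metric = c("stem_bp", "loop_nt"), ordered = TRUE
  ))
  M <- add_ancestor(M)
  expect_equal(unname(M$ancestor), c(12L, 0L))

  # degenerate all-zero stem column
  st0 <- rbind(a = 0L, b = 0L)
  M0 <- add_ancestor(char_matrix(st0, tibble::tibble(
    char_id = "P9.len", kind = "stabilizing", domain = "none",
    metric = "stem_bp", ordered = TRUE
  )))
  expect_equal(unname(M0$ancestor), 0L)

  # invariance: a taxon within the column maxima leaves the ancestor alone
  M2 <- add_ancestor(char_matrix(rbind(st, d = c(5L, 2L)), M$chars))
  expect_equal(M2$ancestor, M$ancestor)
})

test_that("transposition swaps roles, inverts itself, rejects mixed kinds", {
  set.seed(1)
  M <- random_matrix(2, 3, kind = rep("stabilizing", 3))
  Tm <- transpose_matrix(M)
  expect_equal(dim(Tm), c(3L, 2L))
  expect_equal(Tm$orientation, "substructures_as_taxa")
  back <- transpose_matrix(Tm)
  expect_equal(unname(back$states),
               unname(M$states))
  expect_equal(rownames(back$states), rownames(M$states))

  mixed <- random_matrix(4, 4, kind = c("stabilizing", "stabilizing",
                                        "destabilizing", "destabilizing"))
  expect_error(transpose_matrix(mixed), "mixed")
})

test_that("partitions filter characters and taxa with strict contracts", {
  set.seed(2)
  st <- matrix(sample(0:9, 6 * 6, TRUE), 6, 6,
               dimnames = list(sprintf("t%d", 1:6), NULL))
  chars <- tibble::tibble(
    char_id = c("P1.len", "P7.len", "P12.len", "L1.len", "L12.len", "U5.len"),
    kind = c("stabilizing", "stabilizing", "stabilizing",
             "destabilizing", "destabilizing", "destabilizing"),
    domain = c("C", "S", "S", "C", "S", "C"),
    metric = c(rep("stem_bp", 3), rep("loop_nt", 2), "unpaired_nt"),
    ordered = TRUE
  )
  taxa <- tibble::tibble(
    taxon_id = sprintf("t%d", 1:6),
    superkingdom = rep(c("Archaea", "Bacteria", "Eukarya"), 2),
    rpr_type = NA_character_
  )
  M <- char_matrix(st, chars, taxa = taxa)
  expect_equal(ncol(partition_matrix(M, "stabilizing")$states), 3L)
  expect_equal(ncol(partition_matrix(M, "destabilizing")$states), 3L)
  expect_equal(ncol(partition_matrix(M, "domain_S")$states), 3L)
  expect_equal(nrow(partition_matrix(M, "superkingdom:Archaea")$states), 2L)
  expect_error(partition_matrix(M, "core_A"), "P2")
  expect_error(partition_matrix(M, "superkingdom:Viruses"), "empty")
  expect_error(partition_matrix(M, "nonsense"), "unknown")
})

test_that("total evidence concatenation adds unordered columns", {
  set.seed(3)
  M <- add_ancestor(random_matrix(4, 5, kind = rep("stabilizing", 5)))
  seqs <- setNames(
    vapply(1:4, function(i) paste(sample(c("A", "C", "G", "U", "-"), 7,
                                         TRUE), collapse = ""), character(1)),
    rownames(M$states)
  )
  C <- combine_total_evidence(M, seqs)
  expect_equal(ncol(C$states), 12L)            # 5 + 7
  expect_false(any(C$chars$ordered[6:12]))
  expect_true(all(is.na(C$ancestor[6:12])))    # ancestor '?' on sequence
  expect_equal(combine_total_evidence(M, NULL), M)
  names(seqs)[1] <- "zzz"
  expect_error(combine_total_evidence(M, seqs), "taxon")
})

test_that("TSV round trip preserves matrix, metadata and ancestor", {
  set.seed(4)
  M <- add_ancestor(random_matrix(5, 4, kind = rep("stabilizing", 4)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(M, f)
  M2 <- read_matrix_tsv(f)
  expect_equal(M2$states, M$states)
  expect_equal(M2$chars, M$chars)
  expect_equal(M2$ancestor, M$ancestor)
})

test_that("column reflection with kind swap flips the ancestor and keeps lengths", {
  set.seed(5)
  M <- random_matrix(6, 5, kind = rep("stabilizing", 5))
  mx <- apply(M$states, 2, max)
  Mr <- M
  Mr$states <- sweep(-M$states, 2, mx, "+")
  Mr$chars$kind <- "destabilizing"
  a <- add_ancestor(M)$ancestor
  ar <- add_ancestor(Mr)$ancestor
  expect_equal(unname(ar), rep(0L, 5))
  expect_equal(unname(a), unname(mx))
  tr <- ape::rtree(6, tip.label = rownames(M$states))
  expect_equal(tree_length(tr, M), tree_length(tr, Mr))
})
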