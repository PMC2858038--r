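ordered_chars <- function(n) tibble::tibble(
  char_id = sprintf("c%02d", seq_len(n)), kind = "stabilizing",
  domain = "none", metric = "stem_bp", ordered = TRUE
)

test_that("Wagner tree length matches hand-derived and oracle values", {
  # states 0,3,1,2 on ((A,C),(D,B)): brute-force Sankoff gives 3 steps
  tr <- ape::read.tree(text = "((A,C),(D,B));")
  M <- char_matrix(matrix(c(A = 0L, B = 3L, C = 1L, D = 2L), ncol = 1,
                          dimnames = list(c("A", "B", "C", "D"), NULL)),
                   ordered_chars(1))
  expect_equal(tree_length(tr, M), 3)

  # all-identical column costs nothing
  M0 <- char_matrix(matrix(5L, 4, 1, dimnames = list(LETTERS[1:4], NULL)),
                    ordered_chars(1))
  expect_equal(tree_length(tr, M0), 0)

  # two taxa, states 'A' vs '0': ordering forces 10 steps
  t2 <- ape::read.tree(text = "(A,B);")
  M2 <- char_matrix(matrix(c(10L, 0L), 2, 1,
                           dimnames = list(c("A", "B"), NULL)),
                    ordered_chars(1))
  expect_equal(tree_length(t2, M2), 10)
})

test_that("tree length agrees with independent Sankoff implementations", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(4:8, 1); p <- sample(2:6, 1)
    ordv <- sample(c(TRUE, FALSE), p, TRUE)
    M <- random_matrix(n, p, max_state = 6,
                       kind = ifelse(ordv, "stabilizing", "sequence"))
    M$chars$ordered <- ordv
    tr <- ape::rtree(n, tip.label = rownames(M$states))
    mine <- tree_length(tr, M)
    # pure-R recursive Sankoff oracle
    states_tip_order <- M$states[tr$tip.label, , drop = FALSE]
    expect_equal(mine, r_sankoff_length(tr, states_tip_order, ordv))
    # cross-check against phangorn's Sankoff with a linear cost matrix
    lv <- as.character(0:6)
    cost <- outer(0:6, 0:6, function(a, b) abs(a - b))
    dimnames(cost) <- list(lv, lv)
    pd <- phangorn::phyDat(matrix(as.character(M$states), n,
                                  dimnames = dimnames(M$states)),
                           type = "USER", levels = lv)
    ph_all <- sum(phangorn::parsimony(tr, pd, method = "sankoff",
                                      cost = cost))
    pd_fitch_cost <- outer(0:6, 0:6, function(a, b) as.numeric(a != b))
    dimnames(pd_fitch_cost) <- list(lv, lv)
    per_site_ord <- phangorn::parsimony(tr, pd, method = "sankoff",
                                        cost = cost, site = "site")
    per_site_unord <- phangorn::parsimony(tr, pd, method = "sankoff",
                                          cost = pd_fitch_cost,
                                          site = "site")
    mixed <- sum(ifelse(ordv, per_site_ord, per_site_unord))
    expect_equal(mine, mixed)
  }
})

test_that("searches find the analytic optimum on a clean synapomorphy", {
  st <- rbind(A = c(1L, 1L), B = c(1L, 1L), C = c(0L, 0L), D = c(0L, 0L))
  M <- char_matrix(st, ordered_chars(2))
  fit <- mp_search(M, "exhaustive", include_ancestor = FALSE)
  expect_equal(fit$length, 2)
  expect_equal(fit$n_trees, 1L)
  cons <- fit$trees[[1]]
  grp <- ape::prop.part(cons)
  expect_true(any(vapply(grp, function(g) {
    setequal(cons$tip.label[g], c("A", "B")) ||
      setequal(cons$tip.label[g], c("C", "D"))
  }, logical(1))))
})

test_that("heuristic and branch-and-bound match exhaustive enumeration", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(5:7, 1); p <- sample(3:10, 1)
    M <- random_matrix(n, p, kind = rep("stabilizing", p))
    ex <- mp_search(M, "exhaustive", include_ancestor = FALSE,
                    max_trees = 5000)
    bb <- mp_search(M, "branch_and_bound", include_ancestor = FALSE,
                    max_trees = 5000)
    hh <- mp_search(M, "heuristic", reps = 10, seed = i,
                    include_ancestor = FALSE, max_trees = 5000)
    expect_equal(bb$length, ex$length)
    expect_equal(hh$length, ex$length)
    expect_equal(bb$n_trees, ex$n_trees)
    # branch-and-bound never exceeds its stepwise-addition upper bound
    expect_lte(bb$length, bb$initial_bound)
  }
})

test_that("the exhaustive minimal-tree set matches a brute-force oracle", {
  set.seed(32)
  M <- random_matrix(6, 4, max_state = 3, kind = rep("stabilizing", 4))
  ex <- mp_search(M, "exhaustive", include_ancestor = FALSE,
                  max_trees = 5000)
  oracle <- brute_force_min(M$states, rep(TRUE, 4))
  expect_equal(ex$length, oracle$length)
  expect_equal(ex$n_trees, oracle$n_trees)
})

test_that("searched trees are rooted by the ancestor and pruned of it", {
  set.seed(33)
  sim <- simulate_matrix(sim_config(n_taxa = 8, n_stem_chars = 8,
                                    n_loop_chars = 0, seed = 33))
  M <- add_ancestor(sim$matrix)
  fit <- mp_search(M, "heuristic", reps = 5, seed = 3)
  for (tr in fit$trees) {
    expect_false("ANC" %in% tr$tip.label)
    expect_true(ape::is.rooted(tr))
    expect_setequal(tr$tip.label, rownames(M$states))
  }
  # pruning the ancestor never changes the ingroup topology
  for (k in seq_along(fit$trees)) {
    ingroup_unrooted <- ape::unroot(fit$trees[[k]])
    direct <- ape::unroot(ape::drop.tip(fit$trees_unrooted[[k]], "ANC"))
    expect_equal(ape::dist.topo(ingroup_unrooted, direct)[1], 0)
  }
})

test_that("strict consensus keeps shared clades and collapses conflicts", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  expect_true(ape::all.equal.phylo(strict_consensus(list(t1, t1)), t1,
                                   use.edge.length = FALSE))
  t2 <- ape::read.tree(text = "((A,B),((C,D),E));")
  cons <- strict_consensus(list(t1, t2))
  parts <- lapply(ape::prop.part(cons), function(g) sort(cons$tip.label[g]))
  expect_true(list(c("A", "B")) %in% parts ||
              any(vapply(parts, identical, logical(1), c("A", "B"))))
  expect_false(any(vapply(parts, identical, logical(1), c("D", "E"))))
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(strict_consensus(list(t1, t3)), "leaf set")
})

test_that("consistency indices behave on homoplasy-free and forced cases", {
  # clean hierarchical data: CI = RI = 1
  st <- rbind(A = c(0L, 0L), B = c(1L, 0L), C = c(2L, 1L), D = c(2L, 2L))
  M <- char_matrix(st, ordered_chars(2))
  fit <- mp_search(M, "exhaustive", include_ancestor = FALSE)
  stats <- consistency_stats(fit)
  expect_equal(stats$ci, 1)
  expect_equal(stats$ri, 1)
  expect_equal(stats$rc, 1)

  # single binary character on the wrong tree: s=2, m=1 -> CI 0.5
  tr <- ape::read.tree(text = "((A,C),(B,D));")
  Mb <- char_matrix(matrix(c(A = 0L, B = 0L, C = 1L, D = 1L), ncol = 1,
                           dimnames = list(LETTERS[1:4], NULL)),
                    ordered_chars(1))
  s <- tree_length(tr, Mb)
  expect_equal(s, 2)
  m <- 1
  expect_equal(m / s, 0.5)

  # RC = CI * RI by construction
  set.seed(41)
  Mr <- random_matrix(6, 8, kind = rep("stabilizing", 8))
  fr <- mp_search(Mr, "branch_and_bound", include_ancestor = FALSE)
  sr <- consistency_stats(fr)
  expect_equal(sr$rc, sr$ci * sr$ri)
})

test_that("adding characters never decreases tree length", {
  set.seed(42)
  M <- random_matrix(6, 6, kind = rep("stabilizing", 6))
  tr <- ape::rtree(6, tip.label = rownames(M$states))
  lens <- vapply(1:6, function(p) {
    Mp <- M
    Mp$states <- M$states[, 1:p, drop = FALSE]
    Mp$chars <- M$chars[1:p, ]
    tree_length(tr, Mp)
  }, numeric(1))
  expect_true(all(diff(lens) >= 0))
})

test_that("g1 is negative on structured data and errors without variance", {
  sim <- simulate_matrix(sim_config(n_taxa = 12, n_stem_chars = 15,
                                    n_loop_chars = 0, change_rate = 0.1,
                                    seed = 5))
  M <- add_ancestor(sim$matrix)
  g1 <- g1_statistic(M, n_random = 2000, seed = 2)
  expect_lt(as.numeric(g1), 0)
  # direct skewness recomputation from the sampled lengths
  lens <- attr(g1, "lengths")
  skew <- mean((lens - mean(lens))^3) / mean((lens - mean(lens))^2)^1.5
  expect_equal(as.numeric(g1), skew)
  # deterministic given the seed
  expect_equal(as.numeric(g1_statistic(M, n_random = 500, seed = 7)),
               as.numeric(g1_statistic(M, n_random = 500, seed = 7)))

  Mc <- char_matrix(matrix(2L, 5, 2, dimnames = list(letters[1:5], NULL)),
                    ordered_chars(2))
  expect_error(g1_statistic(Mc, n_random = 200, include_ancestor = FALSE),
               "variance")
})

test_that("bootstrap supports clean clades and stays stable across seeds", {
  # twenty identical clean synapomorphies for {A,B,C}
  st <- rbind(A = rep(1L, 20), B = rep(1L, 20), C = rep(1L, 20),
              D = rep(0L, 20), E = rep(0L, 20), F = rep(0L, 20))
  M <- char_matrix(st, ordered_chars(20))
  bt <- mp_bootstrap(M, n_reps = 500, seed = 1, include_ancestor = FALSE)
  keys <- vapply(bt$tips, paste, character(1), collapse = "|")
  hit <- which(keys %in% c("A|B|C", "D|E|F"))
  expect_true(length(hit) >= 1)
  expect_gte(max(bt$support[hit]), 99)

  # a single uninformative character supports nothing strongly
  M1 <- char_matrix(matrix(c(0L, 0L, 0L, 0L, 0L, 1L), 6, 1,
                           dimnames = list(LETTERS[1:6], NULL)),
                    ordered_chars(1))
  b1 <- mp_bootstrap(M1, n_reps = 500, seed = 1, include_ancestor = FALSE)
  if (nrow(b1)) expect_lt(max(b1$support), 50)

  # seed-to-seed stability on simulated data
  sim <- simulate_matrix(sim_config(n_taxa = 10, n_stem_chars = 12,
                                    n_loop_chars = 0, seed = 8))
  Ms <- add_ancestor(sim$matrix)
  bA <- mp_bootstrap(Ms, n_reps = 4000, seed = 11)
  bB <- mp_bootstrap(Ms, n_reps = 4000, seed = 12)
  kA <- vapply(bA$tips, paste, character(1), collapse = "|")
  kB <- vapply(bB$tips, paste, character(1), collapse = "|")
  strong <- kA[bA$support >= 70]
  for (k in strong) {
    expect_true(k %in% kB)
    expect_lt(abs(bA$support[kA == k] - bB$support[kB == k]), 6)
  }
})

test_that("tree length is invariant to per-column state reflection", {
  set.seed(51)
  M <- random_matrix(7, 6, kind = rep("stabilizing", 6))
  Mr <- M
  Mr$states <- sweep(-M$states, 2, apply(M$states, 2, max), "+")
  ex1 <- mp_search(M, "branch_and_bound", include_ancestor = FALSE)
  ex2 <- mp_search(Mr, "branch_and_bound", include_ancestor = FALSE)
  expect_equal(ex1$length, ex2$length)
})

test_that("tidy and glance summarize a fit", {
  set.seed(52)
  M <- add_ancestor(random_matrix(6, 6, kind = rep("stabilizing", 6)))
  fit <- mp_search(M, "branch_and_bound", seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), fit$n_trees)
  expect_true(all(c("tree", "newick", "length") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$length, fit$length)
  expect_true(all(c("ci", "ci_excl", "ri", "rc") %in% names(gl)))
})
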