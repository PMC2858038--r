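# R-side wrappers around the compiled parsimony engine.  States pass to
# C++ as an integer matrix with -1 for missing; ordered columns are
# scored by Wagner (linear) costs, unordered columns by Fitch costs.

states_for_search <- function(M, include_ancestor = TRUE) {
  st <- M$states
  if (include_ancestor) {
    if (is.null(M$ancestor)) {
      abort("matrix has no ancestor row; call add_ancestor() or use include_ancestor = FALSE")
    }
    if ("ANC" %in% rownames(st)) abort("taxon name 'ANC' is reserved")
    st <- rbind(st, ANC = M$ancestor)
  }
  st[is.na(st)] <- -1L
  storage.mode(st) <- "integer"
  st
}

#' Parsimony length of a tree
#'
#' Minimum number of steps needed by the character matrix on the given
#' topology: linearly ordered (Wagner) characters cost `|i - j|` per
#' change, unordered (Fitch) characters cost 1.  The tree may be rooted
#' or unrooted and may contain polytomies; the exact minimum is
#' computed by dynamic programming over the full state space.
#'
#' @param tree a `phylo` whose tip labels are taxa of `M` (plus
#'   optionally `"ANC"` when the ancestor row should be scored).
#' @param M a [char_matrix()].
#' @param per_character return the per-character step vector instead of
#'   the total.
#' @return total steps (numeric scalar) or a per-character vector.
#' @export
tree_length <- function(tree, M, per_character = FALSE) {
  stopifnot(inherits(tree, "phylo"), inherits(M, "char_matrix"))
  st <- states_for_search(M, include_ancestor = "ANC" %in% tree$tip.label)
  missing_taxa <- setdiff(tree$tip.label, rownames(st))
  if (length(missing_taxa)) {
    abort(sprintf("tree tips absent from the matrix: %s",
                  paste(missing_taxa, collapse = ", ")))
  }
  st <- st[tree$tip.label, , drop = FALSE]
  steps <- .cpp_score_tree(matrix(as.integer(tree$edge), ncol = 2),
                           length(tree$tip.label), st, M$chars$ordered)
  names(steps) <- M$chars$char_id
  if (per_character) steps else sum(steps)
}

#' Maximum-parsimony tree search
#'
#' Equally weighted maximum parsimony with three strategies:
#' `exhaustive` enumerates every unrooted binary topology (up to 10
#' leaves), `branch_and_bound` enumerates with pruning below a
#' stepwise-addition upper bound (exact), and `heuristic` runs `reps`
#' random-addition-sequence starts each followed by tree bisection and
#' reconnection (TBR) branch swapping, keeping all equal-length trees
#' (MULTREES behaviour) up to `max_trees`.  When the matrix carries a
#' hypothetical ancestor it is included in the search as an ordinary
#' leaf named `ANC`; each returned tree is then rooted on the branch
#' where the ancestor attaches and the ancestor leaf is pruned, which
#' is what makes the trees intrinsically rooted without any outgroup.
#'
#' @param M a [char_matrix()]; call [add_ancestor()] first for rooted
#'   trees.
#' @param strategy search strategy (see above).
#' @param reps random-addition replicates (heuristic only).
#' @param seed integer seed; all tie-breaking and addition orders are
#'   reproducible from it.
#' @param max_trees cap on retained minimal trees; hitting the cap sets
#'   the `saturated` flag.
#' @param include_ancestor include the ancestor row (and root trees on
#'   it).  Defaults to `TRUE` when the matrix is polarized.
#' @return an object of class `mp_fit` with elements `trees` (rooted,
#'   ancestor pruned — or unrooted when searched without ancestor),
#'   `trees_unrooted` (as searched), `length`, `n_trees`, `saturated`,
#'   `rep_lengths`, `strategy`, `seed`, and the matrix (for later
#'   statistics).
#' @export
mp_search <- function(M, strategy = c("heuristic", "branch_and_bound",
                                      "exhaustive"),
                      reps = 10, seed = 1, max_trees = 10000,
                      include_ancestor = !is.null(M$ancestor)) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(M, "char_matrix"))
  st <- states_for_search(M, include_ancestor)
  n <- nrow(st)
  if (n < 3L) abort("need at least 3 leaves (including any ancestor)")
  if (strategy == "exhaustive" && n > 10L) {
    abort("exhaustive search is limited to 10 leaves; use branch_and_bound or heuristic")
  }
  if (strategy == "branch_and_bound" && n > 25L) {
    abort("branch_and_bound is impractical beyond ~25 leaves; use heuristic")
  }
  ordv <- M$chars$ordered
  res <- if (strategy == "heuristic") {
    .cpp_heuristic(st, ordv, as.integer(reps), as.integer(max_trees),
                   as.integer(seed))
  } else {
    .cpp_enumerate(st, ordv, strategy == "branch_and_bound",
                   as.integer(max_trees), as.integer(seed))
  }
  trees_unrooted <- lapply(res$trees, function(nwk) {
    tr <- ape::read.tree(text = nwk)
    tr$tip.label <- rownames(st)[as.integer(sub("^t", "", tr$tip.label))]
    tr
  })
  class(trees_unrooted) <- "multiPhylo"

  trees <- trees_unrooted
  if (include_ancestor) {
    trees <- lapply(trees_unrooted, function(tr) {
      tr <- ape::root(tr, outgroup = "ANC", resolve.root = TRUE)
      ape::drop.tip(tr, "ANC")
    })
    class(trees) <- "multiPhylo"
  }

  structure(
    list(
      trees = trees,
      trees_unrooted = trees_unrooted,
      length = res$length,
      n_trees = length(trees),
      saturated = res$saturated,
      rep_lengths = res$rep_lengths %||% NULL,
      initial_bound = res$initial_bound %||% NULL,
      strategy = strategy,
      seed = seed,
      rooted = include_ancestor,
      matrix = M
    ),
    class = "mp_fit"
  )
}

#' @export
print.mp_fit <- function(x, ...) {
  cat(sprintf(
    "<mp_fit> %s search: %d minimal tree(s) of length %g%s%s\n",
    x$strategy, x$n_trees, x$length,
    if (x$rooted) ", rooted via hypothetical ancestor" else " (unrooted)",
    if (isTRUE(x$saturated)) " [tree buffer saturated]" else ""
  ))
  invisible(x)
}

#' Strict consensus of a set of trees
#'
#' Retains exactly the clades present in every input tree; conflicting
#' resolutions collapse into polytomies.
#'
#' @param trees a `multiPhylo`, list of `phylo`, or an [mp_search()] fit.
#' @return a `phylo`.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "mp_fit")) trees <- trees$trees
  if (inherits(trees, "phylo")) return(trees)
  if (!length(trees)) abort("no trees to take a consensus of")
  tip_sets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(tip_sets)) != 1L) abort("trees must share one leaf set")
  if (length(trees) == 1L) return(trees[[1]])
  rooted <- ape::is.rooted(trees[[1]])
  out <- ape::consensus(trees, p = 1, rooted = rooted)
  if (rooted) attr(out, "rooted") <- TRUE
  out
}

# per-character minimum conceivable steps (on the best conceivable tree)
char_min_steps <- function(st, ordered) {
  vapply(seq_len(ncol(st)), function(c) {
    x <- st[, c]
    x <- x[x >= 0L]
    if (!length(x)) return(0)
    if (ordered[c]) as.numeric(max(x) - min(x))
    else as.numeric(length(unique(x)) - 1L)
  }, numeric(1))
}

# per-character steps on the completely unresolved (star) tree
char_star_steps <- function(st, ordered) {
  vapply(seq_len(ncol(st)), function(c) {
    x <- st[, c]
    x <- x[x >= 0L]
    if (!length(x)) return(0)
    if (ordered[c]) {
      med <- sort(x)[ceiling(length(x) / 2)]
      as.numeric(sum(abs(x - med)))
    } else {
      as.numeric(length(x) - max(table(x)))
    }
  }, numeric(1))
}

#' Homoplasy statistics of a parsimony result
#'
#' Computes the ensemble consistency index `CI = m/s` (minimum
#' conceivable steps over realized steps), its variant excluding
#' parsimony-uninformative characters, the retention index
#' `RI = (g - s) / (g - m)` where `g` is the star-tree (worst-case)
#' length, and the rescaled index `RC = CI * RI`, on the first minimal
#' tree of the fit (all minimal trees share the length `s`).
#' A character is parsimony-uninformative when its star-tree length
#' equals its minimum length, i.e. it needs the same number of steps on
#' every topology.
#'
#' @param fit an [mp_search()] result.
#' @return a one-row tibble: `length`, `n_trees`, `ci`, `ci_excl`,
#'   `ri`, `rc`.
#' @export
consistency_stats <- function(fit) {
  stopifnot(inherits(fit, "mp_fit"))
  M <- fit$matrix
  st <- states_for_search(M, fit$rooted)
  ordered <- M$chars$ordered
  tr <- fit$trees_unrooted[[1]]
  stt <- st[tr$tip.label, , drop = FALSE]
  s_c <- as.numeric(.cpp_score_tree(matrix(as.integer(tr$edge), ncol = 2),
                                    length(tr$tip.label), stt, ordered))
  m_c <- char_min_steps(st, ordered)
  g_c <- char_star_steps(st, ordered)
  uninf <- g_c <= m_c + 1e-9

  ci_of <- function(m, s) if (s == 0) 1 else m / s
  s <- sum(s_c); m <- sum(m_c); g <- sum(g_c)
  ci <- ci_of(m, s)
  ci_excl <- ci_of(sum(m_c[!uninf]), sum(s_c[!uninf]))
  ri <- if (g > m) (g - s) / (g - m) else if (s <= m) 1 else 0
  tibble(
    length = s, n_trees = fit$n_trees,
    ci = ci, ci_excl = ci_excl, ri = ri, rc = ci * ri
  )
}

#' g1 skewness of the random-tree length distribution
#'
#' Samples `n_random` topologies uniformly at random, scores each, and
#' returns the sample skewness (third standardized moment) of the
#' lengths.  Strongly negative values indicate hierarchical structure
#' in the data; near-zero values indicate little nonrandom signal.
#'
#' @param M a [char_matrix()].
#' @param n_random number of random topologies (>= 100).
#' @param seed integer seed.
#' @param include_ancestor include the polarized ancestor as a leaf.
#' @return the g1 statistic (numeric scalar) with attribute `lengths`.
#' @export
g1_statistic <- function(M, n_random = 10000, seed = 1,
                         include_ancestor = !is.null(M$ancestor)) {
  stopifnot(inherits(M, "char_matrix"))
  if (n_random < 100) abort("n_random must be at least 100")
  st <- states_for_search(M, include_ancestor)
  lens <- .cpp_random_lengths(st, M$chars$ordered, as.integer(n_random),
                              as.integer(seed))
  if (stats::sd(lens) < 1e-12) {
    abort("tree-length distribution has zero variance; g1 undefined")
  }
  m <- mean(lens)
  g1 <- mean((lens - m)^3) / (mean((lens - m)^2))^1.5
  attr(g1, "lengths") <- lens
  g1
}

#' Bootstrap support by fast stepwise addition
#'
#' For each replicate the characters are resampled with replacement and
#' a single stepwise-addition tree is built under a random taxon order
#' with no branch swapping ("fast" bootstrap semantics); clade
#' frequencies are tallied across replicates.  When the matrix carries
#' an ancestor, clades are reported on the rooted (ingroup) side.
#'
#' @param M a [char_matrix()].
#' @param n_reps number of replicates (>= 100).
#' @param seed integer seed.
#' @param include_ancestor include the polarized ancestor as a leaf.
#' @return a tibble with `tips` (list column of sorted taxon names) and
#'   `support` (percentage of replicates containing the clade).
#' @export
mp_bootstrap <- function(M, n_reps = 1000, seed = 1,
                         include_ancestor = !is.null(M$ancestor)) {
  stopifnot(inherits(M, "char_matrix"))
  if (n_reps < 100) abort("n_reps must be at least 100")
  st <- states_for_search(M, include_ancestor)
  res <- .cpp_bootstrap(st, M$chars$ordered, as.integer(n_reps),
                        as.integer(seed))
  labels <- rownames(st)
  anc_idx <- if (include_ancestor) which(labels == "ANC") else 0L
  agg <- new.env(parent = emptyenv())
  for (k in seq_along(res$clade)) {
    idx <- as.integer(strsplit(res$clade[k], ",", fixed = TRUE)[[1]])
    if (anc_idx %in% idx) idx <- setdiff(seq_along(labels), idx)
    idx <- setdiff(idx, anc_idx)
    key <- paste(sort(labels[idx]), collapse = "|")
    agg[[key]] <- (agg[[key]] %||% 0L) + res$count[k]
  }
  keys <- ls(agg)
  out <- tibble(
    tips = lapply(keys, function(k) strsplit(k, "|", fixed = TRUE)[[1]]),
    support = vapply(keys, function(k) 100 * agg[[k]] / n_reps, numeric(1))
  )
  dplyr::arrange(out, dplyr::desc(.data$support))
}

#' Annotate a tree with bootstrap support
#'
#' Writes support percentages (when >= `threshold`) into the node
#' labels of a rooted reporting tree.
#'
#' @param tree a `phylo` (e.g. the strict consensus).
#' @param boot result of [mp_bootstrap()].
#' @param threshold minimum support to report (default 50).
#' @return the tree with `node.label` set.
#' @export
clade_support <- function(tree, boot, threshold = 50) {
  keys <- vapply(boot$tips, function(t) paste(sort(t), collapse = "|"),
                 character(1))
  ntip <- length(tree$tip.label)
  labs <- character(tree$Nnode)
  for (nd in seq_len(tree$Nnode)) {
    tips <- sort(tree$tip.label[unlist(phangorn_free_desc(tree, ntip + nd))])
    hit <- match(paste(tips, collapse = "|"), keys)
    if (!is.na(hit) && boot$support[hit] >= threshold) {
      labs[nd] <- sprintf("%.0f", boot$support[hit])
    }
  }
  tree$node.label <- labs
  tree
}

# tips descending from an internal node (self-contained, no extra deps)
phangorn_free_desc <- function(tree, node) {
  ntip <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k) {
    if (k <= ntip) k else phangorn_free_desc(tree, k)
  }))
}

#' @export
tidy.mp_fit <- function(x, ...) {
  tibble(
    tree = seq_len(x$n_trees),
    newick = vapply(x$trees, function(t) ape::write.tree(t), character(1)),
    length = rep(x$length, x$n_trees)
  )
}

#' @export
glance.mp_fit <- function(x, ...) {
  dplyr::bind_cols(
    consistency_stats(x),
    tibble(strategy = x$strategy, saturated = x$saturated, seed = x$seed)
  )
}
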