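#' Configuration for synthetic structural-character data
#'
#' The generator emulates the polarization model of structural
#' cladistics: a true rooted (Yule) tree of molecules, stabilizing stem
#' characters that start at the maximal ancestral state and erode by a
#' downward-biased bounded random walk, de-stabilizing loop characters
#' that start at 0 and grow, lineage-specific substructure loss, and a
#' known accretion order of substructures born along the root-to-tip
#' spine of the true tree (so basal substructures are the oldest).
#' Loop characters are tied to their stems (loop `i` is the hairpin of
#' stem `i`), which keeps simulated molecules structurally consistent.
#'
#' @param n_taxa number of molecules (>= 4).
#' @param n_stem_chars number of stem-length characters.
#' @param n_loop_chars number of hairpin-loop characters
#'   (<= `n_stem_chars`).
#' @param max_state ancestral (maximal) stem length, <= 61.
#' @param change_rate expected number of state-change events per branch.
#' @param drift probability that an event moves a stem down (a loop
#'   up), i.e. towards the derived direction.
#' @param loss_prob per-lineage probability that a substructure (stem
#'   plus its loop) is lost outright (state 0).
#' @param schedule optional integer vector of birth positions along the
#'   spine (1 = root), one per character; the default spreads the
#'   substructures evenly from the root to the spine tip.
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 20, n_stem_chars = 20, n_loop_chars = 10,
                       max_state = 12, change_rate = 0.2, drift = 0.9,
                       loss_prob = 0.05, schedule = NULL, seed = 1) {
  if (n_taxa < 4) abort("n_taxa must be at least 4")
  if (max_state > 61 || max_state < 1) abort("max_state must be in 1..61")
  if (n_loop_chars > n_stem_chars) {
    abort("n_loop_chars cannot exceed n_stem_chars (loops are tied to stems)")
  }
  if (change_rate < 0 || loss_prob < 0 || loss_prob > 1 ||
      drift < 0 || drift > 1) {
    abort("rates must be non-negative (probabilities within [0,1])")
  }
  structure(
    list(n_taxa = as.integer(n_taxa),
         n_stem_chars = as.integer(n_stem_chars),
         n_loop_chars = as.integer(n_loop_chars),
         max_state = as.integer(max_state),
         change_rate = change_rate, drift = drift, loss_prob = loss_prob,
         schedule = schedule, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate the true tree of molecules
#'
#' A Yule (pure-birth) tree with `n_taxa` leaves, reproducible from the
#' config seed.
#'
#' @param config a [sim_config()].
#' @return a rooted `phylo` with tips `m01`, `m02`, ...
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tr <- ape::rphylo(config$n_taxa, birth = 1, death = 0)
  tr$tip.label <- sprintf("m%02d", seq_len(config$n_taxa))
  tr
}

#' Simulate a character matrix with known ground truth
#'
#' Substructures are born at scheduled positions along the spine (the
#' root-to-deepest-tip path) of the true tree: lineages that diverged
#' from the spine before a substructure's birth lack it entirely
#' (state 0).  Where present, a stem character starts at `max_state`
#' and takes `Pois(change_rate)` events per branch, each moving one
#' state down with probability `drift` (up otherwise), reflected into
#' `[1, max_state]`; its hairpin loop starts at 0 and drifts upward in
#' `[0, max_state]`.  Independently, each lineage loses each
#' substructure (stem and loop together) with probability `loss_prob`.
#'
#' @param config a [sim_config()].
#' @param tree optionally a precomputed tree from [simulate_tree()].
#' @return a list: `matrix` (a [char_matrix()], molecules as taxa) and
#'   `truth` (true tree, per-character birth depth and accretion rank,
#'   spine nodes, config).
#' @export
simulate_matrix <- function(config, tree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(tree)) tree <- simulate_tree(config)
  set.seed(config$seed + 1L)
  ntip <- length(tree$tip.label)
  nS <- config$n_stem_chars
  nL <- config$n_loop_chars
  smax <- config$max_state

  parent <- rep(NA_integer_, ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  depth_of <- function(v) {
    d <- 0L
    while (!is.na(parent[v])) { d <- d + 1L; v <- parent[v] }
    d
  }
  tip_depth <- vapply(seq_len(ntip), depth_of, integer(1))
  deepest <- which.max(tip_depth)
  spine <- rev(c(deepest, {
    v <- parent[deepest]; out <- integer(0)
    while (!is.na(v)) { out <- c(out, v); v <- parent[v] }
    out
  }))[-(tip_depth[deepest] + 1L)]   # internal nodes root..last, drop the tip
  K <- length(spine)

  stem_labels <- sprintf("S%02d", seq_len(nS))
  loop_labels <- sprintf("L%02d", seq_len(nL))
  char_ids <- c(paste0(stem_labels, ".len"),
                if (nL > 0) paste0(loop_labels, ".len"))
  nchar_ <- nS + nL

  # birth position (index into spine) per character
  if (is.null(config$schedule)) {
    mod_birth <- if (nS == 1) 1L else
      1L + floor((seq_len(nS) - 1L) * (K - 1L) / (nS - 1L))
    birth <- c(mod_birth, mod_birth[seq_len(nL)])
  } else {
    birth <- as.integer(config$schedule)
    if (length(birth) != nchar_) {
      abort("schedule length must equal the total number of characters")
    }
    if (max(birth) > K) {
      abort(sprintf(
        "schedule position %d exceeds the spine depth (%d nodes)",
        max(birth), K
      ))
    }
    # a loop cannot predate its stem
    if (nL > 0) {
      li <- nS + seq_len(nL)
      birth[li] <- pmax(birth[li], birth[seq_len(nL)])
    }
  }

  # children lists for preorder traversal
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  states <- matrix(0L, ntip, nchar_,
                   dimnames = list(tree$tip.label, char_ids))

  step_walk <- function(s, is_stem) {
    nev <- stats::rpois(1, config$change_rate)
    lo <- if (is_stem) 1L else 0L
    for (k in seq_len(nev)) {
      dn <- stats::runif(1) < config$drift
      s <- s + if (is_stem) (if (dn) -1L else 1L) else (if (dn) 1L else -1L)
      if (s < lo) s <- lo + (lo - s)
      if (s > smax) s <- smax - (s - smax)
    }
    s
  }

  for (ch in seq_len(nchar_)) {
    is_stem <- ch <= nS
    v0 <- spine[birth[ch]]
    s0 <- if (is_stem) smax else 0L
    # preorder from the birth node
    walk <- function(v, s) {
      if (v <= ntip) {
        states[v, ch] <<- s
        return(invisible())
      }
      for (u in kids[[as.character(v)]]) {
        walk(u, step_walk(s, is_stem))
      }
    }
    if (v0 <= ntip) states[v0, ch] <- s0 else walk(v0, s0)
  }

  # lineage-specific loss of whole substructures (stem + tied loop)
  if (config$loss_prob > 0) {
    for (m in seq_len(nS)) {
      lost <- stats::runif(ntip) < config$loss_prob
      states[lost, m] <- 0L
      if (m <= nL) states[lost, nS + m] <- 0L
    }
  }

  chars <- tibble(
    char_id = char_ids,
    kind = rep(c("stabilizing", "destabilizing"), c(nS, nL)),
    domain = "none",
    metric = rep(c("stem_bp", "loop_nt"), c(nS, nL)),
    ordered = TRUE
  )
  M <- char_matrix(states, chars)
  truth <- list(
    tree = tree,
    birth_depth = setNames(birth, char_ids),
    accretion_rank = setNames(rank(birth, ties.method = "min"), char_ids),
    spine = spine,
    config = config
  )
  list(matrix = M, truth = truth)
}

#' Emit dot-bracket molecules that code back to a matrix
#'
#' Builds, for every taxon of a simulated matrix, a secondary structure
#' whose decomposition and labeling reproduce the matrix exactly: each
#' stem character with state `s > 0` becomes a hairpin module of `s`
#' base pairs whose loop length is the state of its tied loop character
#' (3 unannotated filler nucleotides when the stem has no loop
#' character).  Absent substructures (state 0) emit nothing.  The
#' function also returns the annotation table and the homology scheme
#' needed to re-code the structures.
#'
#' @param M a [char_matrix()] from [simulate_matrix()] (molecules as
#'   taxa; loop character `i` tied to stem character `i`).
#' @return a list: `structures` (list of
#'   [secondary_structure][parse_structure]), `annotation` (tibble,
#'   1-based), `scheme` (a [homology_scheme()]).
#' @export
simulate_molecules <- function(M) {
  stopifnot(inherits(M, "char_matrix"))
  stem_idx <- which(M$chars$kind == "stabilizing")
  loop_idx <- which(M$chars$kind == "destabilizing")
  stem_labels <- sub("\\.len$", "", M$chars$char_id[stem_idx])
  loop_labels <- sub("\\.len$", "", M$chars$char_id[loop_idx])
  nS <- length(stem_idx)
  nL <- length(loop_idx)

  scheme <- homology_scheme(
    c(stem_labels, loop_labels),
    c(rep("stem", nS), rep("hairpin", nL))
  )

  structures <- list()
  ann <- list()
  for (tx in rownames(M$states)) {
    seq_parts <- character(0)
    db_parts <- character(0)
    pos <- 0L  # 0-based next position
    for (m in seq_len(nS)) {
      s <- M$states[tx, stem_idx[m]]
      h <- if (m <= nL) M$states[tx, loop_idx[m]] else NA_integer_
      if (s == 0L) {
        if (!is.na(h) && h > 0L) {
          abort(sprintf(
            "inconsistent states in %s: loop %s > 0 while stem %s is absent",
            tx, loop_labels[m], stem_labels[m]
          ))
        }
        next
      }
      hlen <- if (is.na(h)) 3L else h
      left <- sample(c("G", "C", "A", "U"), s, replace = TRUE)
      comp <- c(G = "C", C = "G", A = "U", U = "A")
      seq_parts <- c(seq_parts, paste(left, collapse = ""),
                     strrep("A", hlen),
                     paste(rev(unname(comp[left])), collapse = ""))
      db_parts <- c(db_parts, strrep("(", s), strrep(".", hlen),
                    strrep(")", s))
      ann[[length(ann) + 1L]] <- tibble(
        molecule_id = tx,
        start = c(pos + 1L, pos + s + hlen + 1L),
        end = c(pos + s, pos + 2L * s + hlen),
        label = stem_labels[m]
      )
      if (!is.na(h) && h > 0L) {
        ann[[length(ann) + 1L]] <- tibble(
          molecule_id = tx, start = pos + s + 1L, end = pos + s + hlen,
          label = loop_labels[m]
        )
      }
      pos <- pos + 2L * s + hlen
    }
    if (pos == 0L) {
      abort(sprintf("molecule %s has no substructures (zero length)", tx))
    }
    structures[[tx]] <- parse_structure(
      paste(db_parts, collapse = ""), "dotbracket",
      sequence = paste(seq_parts, collapse = ""), molecule_id = tx
    )
  }
  list(structures = structures,
       annotation = dplyr::bind_rows(ann),
       scheme = scheme)
}
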