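# Shared fixtures and independent oracles for the test suite.

# random ordered/mixed character matrix wrapped as char_matrix
random_matrix <- function(n_taxa, n_chars, max_state = 9,
                          ordered = rep(TRUE, n_chars),
                          kind = NULL) {
  st <- matrix(sample(0:max_state, n_taxa * n_chars, replace = TRUE),
               n_taxa, n_chars,
               dimnames = list(sprintf("tax%02d", seq_len(n_taxa)), NULL))
  if (is.null(kind)) kind <- ifelse(ordered, "stabilizing", "sequence")
  char_matrix(st, tibble::tibble(
    char_id = sprintf("c%02d", seq_len(n_chars)),
    kind = kind, domain = "none",
    metric = ifelse(ordered, "stem_bp", "aligned_site"),
    ordered = ordered
  ))
}

# Independent pure-R Sankoff oracle: exact minimal steps of `tree` for
# states (rows in tip-number order), linear costs when ordered, 0/1
# otherwise.  Deliberately naive - recursion plus full transition scans.
r_sankoff_length <- function(tree, states, ordered) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  S <- max(states) + 1L
  total <- 0
  for (cc in seq_len(ncol(states))) {
    costfun <- function(node) {
      if (node <= ntip) {
        v <- rep(Inf, S)
        v[states[node, cc] + 1L] <- 0
        return(v)
      }
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      v <- rep(0, S)
      for (k in kids) {
        ck <- costfun(k)
        trans <- vapply(seq_len(S), function(x) {
          if (ordered[cc]) min(ck + abs(seq_len(S) - x))
          else min(ck + as.numeric(seq_len(S) != x))
        }, numeric(1))
        v <- v + trans
      }
      v
    }
    total <- total + min(costfun(root))
  }
  total
}

# brute-force minimum over every unrooted topology (oracle for searches)
brute_force_min <- function(states, ordered) {
  n <- nrow(states)
  alls <- phangorn::allTrees(n, rooted = FALSE)
  best <- Inf
  n_best <- 0L
  for (tr in alls) {
    # multiPhylo stores tip labels on the container, not the elements
    tr$tip.label <- paste0("t", seq_len(n))
    s <- r_sankoff_length(tr, states, ordered)
    if (s < best - 1e-9) {
      best <- s
      n_best <- 1L
    } else if (abs(s - best) <= 1e-9) {
      n_best <- n_best + 1L
    }
  }
  list(length = best, n_trees = n_best)
}

# small labeled toy molecule used across structure tests
toy_molecule <- function() {
  parse_structure(
    "((((...))))..(((....)))", "dotbracket",
    sequence = "GGGGAAACCCCAAGGGUUUUCCC",
    molecule_id = "toy"
  )
}

toy_scheme <- function() {
  homology_scheme(
    c("P1", "P2", "L1", "L2", "J1"),
    c("stem", "stem", "hairpin", "hairpin", "joint")
  )
}

toy_annotation <- function() {
  tibble::tibble(
    molecule_id = "toy",
    start = c(1L, 8L, 5L, 14L, 21L, 17L, 12L),
    end = c(4L, 11L, 7L, 16L, 23L, 20L, 13L),
    label = c("P1", "P1", "L1", "P2", "P2", "L2", "J1")
  )
}

# random dot-bracket structure built from nested hairpin modules and
# spacers; used for property tests of the decomposition
random_structure <- function(seed) {
  set.seed(seed)
  k <- sample(1:4, 1)
  parts <- character(0)
  for (m in seq_len(k)) {
    s <- sample(1:6, 1)
    h <- sample(1:5, 1)
    parts <- c(parts, strrep(".", sample(0:3, 1)),
               strrep("(", s), strrep(".", h), strrep(")", s))
  }
  parts <- c(parts, strrep(".", sample(0:3, 1)))
  db <- paste(parts, collapse = "")
  parse_structure(db, "dotbracket", molecule_id = sprintf("rnd%d", seed))
}
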