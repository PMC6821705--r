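# Shared in-code fixtures: tiny structures built directly from atom tables,
# hand-written PDB records, and one cached ribonucleoprotein fixture reused
# by the slower pipeline tests.

atoms_tbl <- function(name, x, y, z, residue_name, chain = "A", resno = 1L,
                      element = NULL, b = 20, occ = 1) {
  n <- length(name)
  tibble::tibble(
    name = name,
    element = element %||% substr(gsub("[0-9']", "", name), 1, 1),
    x = x, y = y, z = z,
    residue_name = rep_len(residue_name, n),
    chain = rep_len(chain, n),
    resno = as.integer(rep_len(resno, n)),
    insert = "", b_factor = rep_len(b, n),
    occupancy = rep_len(occ, n), altloc = "")
}

`%||%` <- rlang::`%||%`

structure_from_atoms <- function(atoms) rnasurf:::new_complex_structure(atoms)

# A single alanine residue (5 heavy atoms) as fixed-width PDB text.
ala_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 20.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 20.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 20.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00 20.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00 20.00           C",
    "END")
}

# One adenosine nucleotide (full heavy atoms) as PDB text, from the package's
# idealized geometry.
adenosine_pdb_file <- function() {
  at <- rnasurf:::place_nucleotide("A", c(0, 0, 0), diag(3))
  tmp <- tempfile(fileext = ".pdb")
  st <- structure_from_atoms(atoms_tbl(rownames(at), at[, 1], at[, 2],
                                       at[, 3], "A", chain = "B"))
  write_structure(st, tmp)
  tmp
}

# Cached small ribonucleoprotein fixture + surface grid, shared across tests.
shared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- make_complex_fixture(fixture_spec(20, 3, rng_seed = 11,
                                              sequence = c("A", "G", "C")))
      grid <- filter_surface_band(generate_lattice(fx$structure))
      cache <<- list(fx = fx, grid = grid)
    }
    cache
  }
})

# Independent brute-force maximal-clique enumeration over all vertex subsets.
brute_force_max_cliques <- function(adj) {
  adj <- adj > 0
  diag(adj) <- FALSE
  n <- nrow(adj)
  is_clique <- function(v) {
    if (length(v) <= 1) return(TRUE)
    all(adj[v, v][upper.tri(diag(length(v)))])
  }
  cliques <- list()
  for (m in seq_len(2^n) - 1L) {
    v <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    if (length(v) == 0 || !is_clique(v)) next
    extendable <- any(vapply(setdiff(seq_len(n), v), function(u)
      all(adj[u, v]), logical(1)))
    if (!extendable) cliques[[length(cliques) + 1L]] <- v
  }
  cliques
}

canonical_cliques <- function(cl) {
  sort(vapply(cl, function(v) paste(sort(v), collapse = "-"), ""))
}

# Exhaustive path enumeration oracle for the fixed-HMM score.
brute_force_hmm_q <- function(scorer, letters) {
  k <- nrow(scorer$states)
  n <- length(letters)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- -Inf
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    if (p[1] != scorer$start) next
    q <- 0
    ok <- TRUE
    for (t in seq_len(n)) {
      q <- q + log2(scorer$emissions[p[t], letters[t]])
      if (t < n) {
        tr <- scorer$transitions[p[t], p[t + 1]]
        if (tr == 0) { ok <- FALSE; break }
        q <- q + log2(tr)
      }
    }
    if (ok && q > best) best <- unname(q)
  }
  best
}

# Random toy markov scorer with rank-consistent (acyclic) transitions.
random_toy_scorer <- function(k, seed) {
  set.seed(seed)
  centers <- matrix(runif(k * 3, 0, 10), k)
  em <- matrix(runif(k * 4, 0.05, 1), k)
  em <- em / rowSums(em)
  colnames(em) <- c("A", "G", "C", "U")
  start <- sample.int(k, 1)
  d <- sqrt(colSums((t(centers) - centers[start, ])^2))
  rk <- rank(-d, ties.method = "min")
  tr <- matrix(runif(k * k), k) * outer(rk, rk, ">")
  tr <- rnasurf:::row_normalize(tr)
  structure(list(states = tibble::tibble(state = seq_len(k),
                                         x = centers[, 1], y = centers[, 2],
                                         z = centers[, 3]),
                 emissions = em, transitions = tr, start = start,
                 ranks = tibble::tibble(state = seq_len(k),
                                        dist_from_start = d, rank = rk)),
            class = "markov_scorer")
}

uniform_scores <- function(n) {
  p <- matrix(1 / 7, n, 7)
  colnames(p) <- paste0("prob_", c("X", "P", "R", "A", "G", "C", "U"))
  tibble::as_tibble(p)
}
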