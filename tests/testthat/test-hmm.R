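# Voronoi state construction, transition estimation, and the fixed-HMM
# dynamic program against exhaustive path enumeration.

# A small planted scenario shared by several tests: one aligned placement
# whose three base nodes are far apart, with surface scores favoring a
# distinct base at each node.
planted_scenario <- function() {
  nodes <- tibble::tibble(resno = rep(1:3, each = 3),
                          kind = rep(c("P", "R", "b"), 3),
                          x = rep(c(0, 10, 20), each = 3) +
                            rep(c(0, 1, 2), 3),
                          y = rep(c(0, 1, 2), 3), z = 0)
  nodes$kind[nodes$kind == "b"] <- c("A", "G", "U")
  placements <- tibble::tibble(model = 1L, sequence = "AGU",
                               clique_size = 9L, rmsd = 0,
                               matched = list(NULL),
                               aligned_nodes = list(nodes))
  base_nodes <- nodes[nodes$kind %in% c("A", "G", "U"), ]
  grid <- base_nodes[, c("x", "y", "z")]
  sc <- uniform_scores(3)
  sc$prob_A <- c(.6, .1, .1); sc$prob_G <- c(.1, .6, .1)
  sc$prob_C <- .05; sc$prob_U <- c(.05, .05, .55)
  list(placements = placements, grid = grid, scores = sc,
       anchor = as.numeric(base_nodes[1, c("x", "y", "z")]))
}

test_that("state space construction assigns nodes to nearest centers", {
  ps <- planted_scenario()
  sc <- build_state_space(ps$placements, k = 3, ps$scores, ps$grid,
                          seed = 1)
  expect_equal(nrow(sc$states), 3)
  expect_equal(rowSums(sc$emissions), rep(1, 3))
  centers <- cbind(sc$states$x, sc$states$y, sc$states$z)
  bn <- sc$base_nodes
  for (i in seq_len(nrow(bn))) {
    d <- sqrt(colSums((t(centers) - c(bn$x[i], bn$y[i], bn$z[i]))^2))
    expect_equal(bn$state[i], which.min(d))
  }
  expect_error(build_state_space(ps$placements, k = 10, ps$scores, ps$grid),
               "exceeds")
})

test_that("coincident base nodes collapse to a single state", {
  ps <- planted_scenario()
  nodes <- ps$placements$aligned_nodes[[1]]
  nodes$x <- 1; nodes$y <- 1; nodes$z <- 1
  ps$placements$aligned_nodes[[1]] <- nodes
  grid <- tibble::tibble(x = 1, y = 1, z = 1)
  sc <- build_state_space(ps$placements, k = 1, ps$scores[1, ], grid,
                          seed = 1)
  expect_equal(nrow(sc$states), 1)
  expect_equal(c(sc$states$x, sc$states$y, sc$states$z), c(1, 1, 1))
})

test_that("transition counts are symmetrized and direction-pruned", {
  ps <- planted_scenario()
  sc <- build_state_space(ps$placements, k = 3, ps$scores, ps$grid,
                          seed = 1)
  sc <- estimate_transitions(sc, start_anchor = ps$anchor)
  # single placement visiting three cells: chain transitions only
  expect_equal(sum(sc$counts_symmetrized), 4)   # 2 consecutive pairs x 2
  expect_true(all(sc$counts_symmetrized ==
                    t(sc$counts_symmetrized)))
  # start state outgoing mass sums to one; graph is acyclic by rank
  expect_equal(sum(sc$transitions[sc$start, ]), 1)
  rk <- sc$ranks$rank
  pos <- which(sc$transitions > 0, arr.ind = TRUE)
  expect_true(all(rk[pos[, 1]] > rk[pos[, 2]]))
  q <- score_sequence(sc, "AGU")
  expect_equal(q$path, order(-rk))
})

test_that("symmetrization adds forward and backward counts", {
  ps <- planted_scenario()
  sc <- build_state_space(ps$placements, k = 3, ps$scores, ps$grid,
                          seed = 1)
  # fabricate counts c(1->2)=3, c(2->1)=1 via repeated placements
  bn <- sc$base_nodes[1:2, ]
  reps <- dplyr::bind_rows(
    lapply(1:3, function(i) dplyr::mutate(bn, placement = i)),
    dplyr::mutate(bn[2:1, ], resno = 1:2, placement = 4L))
  sc$base_nodes <- reps
  expect_warning(sc2 <- estimate_transitions(sc, start_anchor = ps$anchor),
                 "unreachable")
  a <- sc2$base_nodes$state[1]; b <- sc2$base_nodes$state[2]
  expect_equal(sc2$counts_symmetrized[a, b], 4)
  expect_equal(sc2$counts_symmetrized[b, a], 4)
})

test_that("the dynamic program matches exhaustive path enumeration", {
  for (seed in 1:100) {
    k <- 2 + (seed %% 5)              # 2..6 states
    n <- 1 + (seed %% 4)              # sequences of length 1..4
    scorer <- random_toy_scorer(k, seed)
    letters <- sample(c("A", "G", "C", "U"), n, replace = TRUE)
    brute <- brute_force_hmm_q(scorer, letters)
    if (!is.finite(brute)) {
      expect_error(score_sequence(scorer, paste(letters, collapse = "")),
                   "longest")
    } else {
      dp <- score_sequence(scorer, paste(letters, collapse = ""))
      expect_equal(dp$Q, brute, tolerance = 1e-10)
      expect_lte(dp$Q, 0)
    }
  }
})

test_that("score bounds and degenerate cases behave", {
  # one state, p(A) = 0.5: Q = -1 for "A"
  s1 <- random_toy_scorer(1, 1)
  s1$emissions[1, ] <- c(A = 0.5, G = 0.3, C = 0.1, U = 0.1)
  expect_equal(score_sequence(s1, "A")$Q, -1)
  # all emissions and transitions 1: Q = 0
  s2 <- random_toy_scorer(3, 2)
  s2$emissions[, ] <- 1
  s2$transitions[s2$transitions > 0] <- 1
  expect_equal(score_sequence(s2, "AGU")$Q, 0)
  expect_error(score_sequence(s2, "ATU"), "invalid RNA letter")
})

test_that("pwm-mode scoring slides gap-free windows", {
  logo <- tibble::tibble(
    position = 1:4, kind = "A",
    prob_X = 0, prob_P = 0, prob_R = 0,
    prob_A = c(.7, .1, .5, .25), prob_G = c(.1, .7, .3, .25),
    prob_C = c(.1, .1, .1, .25), prob_U = c(.1, .1, .1, .25),
    height_A = 0, height_G = 0, height_C = 0, height_U = 0,
    info_bits = 0, gap = c(FALSE, FALSE, FALSE, TRUE), n_points = 1L)
  class(logo) <- c("rnasurf_logo", class(logo))
  sc <- pwm_scorer(logo)
  q <- score_sequence(sc, "AG", mode = "pwm")
  expect_equal(q$Q, log2(.7) + log2(.7))
  expect_equal(q$path, c(1, 2))
  # windows overlapping the gap are excluded
  expect_error(score_sequence(sc, "AGAU", mode = "pwm"), "gap-free")
  expect_error(score_sequence(sc, "AGAUU", mode = "pwm"), "longer")
})

test_that("scorer serialization round-trips through the text format", {
  ps <- planted_scenario()
  sc <- build_state_space(ps$placements, k = 3, ps$scores, ps$grid,
                          seed = 1)
  sc <- estimate_transitions(sc, start_anchor = ps$anchor)
  tmp <- withr::local_tempfile()
  write_markov_scorer(sc, tmp)
  lines <- readLines(tmp)
  expect_true(any(grepl("^\\[states\\]", lines)))
  expect_true(any(grepl("^\\[transitions\\]", lines)))
  td <- tidy(sc)
  expect_equal(nrow(td), 3)
  gl <- glance(sc)
  expect_equal(gl$n_states, 3)
  expect_equal(gl$longest_path, 3)
})
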