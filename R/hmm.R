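## Fixed hidden Markov model over Voronoi states: hypothetical base
## locations are k-means cells over aligned base-node positions, emissions
## are surface score vectors averaged around cell centers and renormalized
## over the four bases, transitions are symmetrized counts of
## consecutive-base cell pairs within aligned cliques, and the 5'->3'
## direction is imposed by ranking cells by distance from a start cell. The
## score of an RNA letter sequence is
## Q = max over paths of sum_i log2(p_i(b) T_{i,i+1}), computed by dynamic
## programming over the rank-ordered DAG; with known base locations and
## T = 1 the score reduces to an ordinary PWM sliding score.

#' Build the Voronoi state space of the sequence scorer
#'
#' Runs seeded k-means over the aligned base-node positions of accepted
#' placements; each cell becomes one hidden state whose emission
#' distribution is the mean of the surface score vectors within `radius` of
#' the cell center, renormalized over A/G/C/U.
#'
#' @param placements Accepted placements from [align_cliques()].
#' @param k Number of states (must not exceed the number of distinct
#'   base-node positions).
#' @param point_scores Surface score tibble (`prob_*` columns) aligned with
#'   `grid`.
#' @param grid Grid tibble.
#' @param seed Integer seed for k-means.
#' @param radius Emission averaging radius (A).
#' @return A `markov_scorer` skeleton: `states` (centers), `emissions`
#'   (k x 4 matrix over A/G/C/U), `base_nodes` (per-placement base nodes
#'   with state assignment); transitions unset until
#'   [estimate_transitions()].
#' @export
build_state_space <- function(placements, k, point_scores, grid, seed = 1L,
                              radius = 3) {
  if (nrow(placements) == 0) abort("no accepted placements")
  bn <- dplyr::bind_rows(lapply(seq_len(nrow(placements)), function(i) {
    nodes <- placements$aligned_nodes[[i]]
    nodes <- nodes[nodes$kind %in% BASES, , drop = FALSE]
    nodes$placement <- i
    nodes
  }))
  pts <- cbind(bn$x, bn$y, bn$z)
  n_distinct <- nrow(unique(round(pts, 6)))
  if (k > n_distinct) {
    abort(sprintf("k = %d exceeds the %d distinct base-node positions",
                  k, n_distinct))
  }
  if (k == n_distinct) {
    ## one state per distinct base-node position (exact Voronoi seeds)
    centers <- unique(round(pts, 6))
    bn$state <- max.col(-cross_dist(pts, centers), ties.method = "first")
  } else {
    km <- with_seed(seed, kmeans(pts, centers = k, nstart = 10L,
                                 iter.max = 100L))
    centers <- km$centers
    bn$state <- km$cluster
  }
  emissions <- matrix(0, k, 4, dimnames = list(NULL, BASES))
  for (s in seq_len(k)) {
    avg <- average_scores_at_base(point_scores, grid, centers[s, ], radius)
    p <- as.numeric(avg[1, paste0("prob_", BASES)])
    if (avg$n_points == 0 || sum(p) == 0) {
      warn(sprintf("state %d has no surface scores within %.1f A; uniform emission",
                   s, radius))
      p <- rep(1, 4)
    }
    emissions[s, ] <- p / sum(p)
  }
  structure(list(states = tibble::tibble(state = seq_len(k),
                                         x = centers[, 1], y = centers[, 2],
                                         z = centers[, 3]),
                 emissions = emissions, base_nodes = bn,
                 transitions = NULL, start = NULL, ranks = NULL),
            class = "markov_scorer")
}

#' Estimate directed transition probabilities of the scorer
#'
#' Counts consecutive-base state pairs within each placement, symmetrizes
#' the counts, picks the start state (nearest the supplied anchor, or the
#' cell maximizing summed distance to all others), ranks states by distance
#' from the start, zeroes every edge that does not strictly decrease the
#' rank (i.e. paths move strictly away from the start; lateral equal-rank
#' moves are forbidden) and renormalizes rows. States unreachable from the
#' start are dropped with a warning. The start state carries probability 1.
#'
#' @param scorer A `markov_scorer` skeleton from [build_state_space()].
#' @param start_anchor Optional length-3 coordinate of the 5' pocket anchor.
#' @return The completed `markov_scorer` with `transitions`, `start`,
#'   `ranks` and `counts_symmetrized`.
#' @export
estimate_transitions <- function(scorer, start_anchor = NULL) {
  stopifnot(inherits(scorer, "markov_scorer"))
  k <- nrow(scorer$states)
  counts <- matrix(0, k, k)
  bn <- scorer$base_nodes
  for (pl in unique(bn$placement)) {
    sub <- bn[bn$placement == pl, , drop = FALSE]
    sub <- sub[order(sub$resno), , drop = FALSE]
    if (nrow(sub) < 2) next
    for (j in seq_len(nrow(sub) - 1)) {
      if (sub$resno[j + 1] == sub$resno[j] + 1) {
        a <- sub$state[j]; b <- sub$state[j + 1]
        counts[a, b] <- counts[a, b] + 1
      }
    }
  }
  sym <- counts + t(counts)
  centers <- cbind(scorer$states$x, scorer$states$y, scorer$states$z)
  start <- if (!is.null(start_anchor)) {
    which.min(sqrt(colSums((t(centers) - as.numeric(start_anchor))^2)))
  } else {
    d <- cross_dist(centers, centers)
    which.max(rowSums(d))
  }
  dist_start <- sqrt(colSums((t(centers) - centers[start, ])^2))
  ## rank: the start holds the highest rank; rank strictly decreases with
  ## distance from the start, so admissible paths move strictly outward
  rk <- rank(-dist_start, ties.method = "min")
  trans <- sym
  allowed <- outer(rk, rk, ">")   # from high rank to strictly lower
  trans[!allowed] <- 0
  trans <- row_normalize(trans)
  ## reachability from the start over positive directed edges
  reach <- rep(FALSE, k); reach[start] <- TRUE
  repeat {
    new <- reach | (as.logical(colSums(trans[reach, , drop = FALSE] > 0)))
    if (identical(new, reach)) break
    reach <- new
  }
  if (!all(reach)) {
    warn(sprintf("%d state(s) unreachable from the start cell; dropped",
                 sum(!reach)))
    keep <- which(reach)
    remap <- match(seq_len(k), keep)
    scorer$states <- scorer$states[keep, , drop = FALSE]
    scorer$states$state <- seq_along(keep)
    scorer$emissions <- scorer$emissions[keep, , drop = FALSE]
    scorer$base_nodes <- scorer$base_nodes[scorer$base_nodes$state %in% keep, ]
    scorer$base_nodes$state <- remap[scorer$base_nodes$state]
    sym <- sym[keep, keep, drop = FALSE]
    trans <- row_normalize(trans[keep, keep, drop = FALSE])
    dist_start <- dist_start[keep]
    start <- remap[start]
    k <- length(keep)
  }
  scorer$counts_symmetrized <- sym
  scorer$transitions <- trans
  scorer$start <- start
  scorer$ranks <- tibble::tibble(state = seq_len(k),
                                 dist_from_start = dist_start,
                                 rank = rank(-dist_start,
                                             ties.method = "min"))
  scorer
}

#' @export
print.markov_scorer <- function(x, ...) {
  cat("<markov_scorer> ", nrow(x$states), " Voronoi state(s)",
      if (!is.null(x$transitions)) sprintf(", start state %d", x$start)
      else " (transitions not yet estimated)", "\n", sep = "")
  invisible(x)
}

#' Build a PWM-mode scorer from a logo matrix
#'
#' With predetermined base locations every transition is certain
#' (`T = 1`), so the sequence score reduces to a position weight matrix
#' over the strand positions; per-position probabilities are renormalized
#' over A/G/C/U and gap positions break the admissible windows.
#'
#' @param logo An `rnasurf_logo` from [build_logo()].
#' @return A `pwm_scorer` with `probs` (positions x 4) and `gap`.
#' @export
pwm_scorer <- function(logo) {
  probs <- as.matrix(logo[, paste0("prob_", BASES)])
  colnames(probs) <- BASES
  s <- rowSums(probs)
  ok <- s > 0
  probs[ok, ] <- probs[ok, , drop = FALSE] / s[ok]
  structure(list(probs = probs, gap = logo$gap), class = "pwm_scorer")
}

check_rna_letters <- function(seq) {
  letters <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(letters), BASES)
  if (length(bad)) {
    abort(paste0("invalid RNA letter(s): ", paste(bad, collapse = ", ")))
  }
  letters
}

#' Score an RNA letter sequence against a surface scorer
#'
#' In `pwm` mode (a `pwm_scorer`): `Q` is the maximum over contiguous,
#' gap-free windows of native strand positions of
#' `sum_i log2 p_i(b_i)`. In `hidden` mode (a `markov_scorer` with
#' estimated transitions): `Q` is the maximum over admissible state paths of
#' length `N` starting at the start state of
#' `sum_i log2(p_i(b_i) * T_{i,i+1})` (the final transition factor is 1),
#' computed by dynamic programming over the rank-ordered DAG. `Q <= 0`
#' always, with equality only when every factor on the optimal path is 1.
#'
#' @param scorer A `pwm_scorer` or a completed `markov_scorer`.
#' @param seq RNA letter sequence over A/G/C/U.
#' @param mode `"pwm"` or `"hidden"`; defaults to the scorer's class.
#' @return List with `Q` (bits) and `path` (window positions or state
#'   sequence attaining the maximum).
#' @export
score_sequence <- function(scorer, seq, mode = NULL) {
  mode <- mode %||% if (inherits(scorer, "pwm_scorer")) "pwm" else "hidden"
  mode <- match.arg(mode, c("pwm", "hidden"))
  letters <- check_rna_letters(seq)
  n <- length(letters)
  if (n < 1) abort("sequence must have length >= 1")
  if (mode == "pwm") {
    if (!inherits(scorer, "pwm_scorer")) abort("pwm mode needs a pwm_scorer")
    np <- nrow(scorer$probs)
    if (n > np) abort("sequence longer than the number of strand positions")
    best <- -Inf; best_off <- NA_integer_
    for (off in 0:(np - n)) {
      pos <- off + seq_len(n)
      if (any(scorer$gap[pos])) next
      q <- sum(log2(scorer$probs[cbind(pos, match(letters, BASES))]))
      if (is.na(best_off) || q > best) { best <- q; best_off <- off }
    }
    if (is.na(best_off)) {
      abort("no gap-free window of the required length")
    }
    return(list(Q = best, path = best_off + seq_len(n)))
  }
  if (!inherits(scorer, "markov_scorer") || is.null(scorer$transitions)) {
    abort("hidden mode needs a markov_scorer with estimated transitions")
  }
  k <- nrow(scorer$states)
  loge <- log2(scorer$emissions)
  logt <- suppressWarnings(log2(scorer$transitions))
  v <- rep(-Inf, k); back <- matrix(NA_integer_, n, k)
  v[scorer$start] <- loge[scorer$start, letters[1]]
  if (n > 1) {
    for (t in 2:n) {
      vn <- rep(-Inf, k)
      for (s in seq_len(k)) {
        cand <- v + logt[, s]
        b <- which.max(cand)
        if (is.finite(cand[b])) {
          vn[s] <- cand[b] + loge[s, letters[t]]
          back[t, s] <- b
        }
      }
      v <- vn
    }
  }
  if (!any(is.finite(v))) {
    abort("sequence length exceeds the longest admissible state path")
  }
  end <- which.max(v)
  path <- integer(n); path[n] <- end
  if (n > 1) for (t in n:2) path[t - 1] <- back[t, path[t]]
  list(Q = v[end], path = path)
}

#' Serialize a Markov scorer to a text format
#'
#' Sections: states (centers, rank, distance from start), emissions,
#' symmetrized counts and transition matrix, start state.
#'
#' @param scorer A completed `markov_scorer`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markov_scorer <- function(scorer, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# markov_scorer v1", con)
  writeLines(sprintf("start\t%d", scorer$start), con)
  writeLines("[states]", con)
  st <- scorer$states
  st$rank <- scorer$ranks$rank
  st$dist_from_start <- scorer$ranks$dist_from_start
  utils::write.table(st, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("[emissions]", con)
  utils::write.table(scorer$emissions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("[transitions]", con)
  utils::write.table(scorer$transitions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Tidy a Markov scorer into one row per state
#'
#' @param x A `markov_scorer`.
#' @param ... Unused.
#' @return Tibble: state, center coordinates, rank, distance from start and
#'   emission probabilities.
#' @method tidy markov_scorer
#' @export
tidy.markov_scorer <- function(x, ...) {
  out <- x$states
  if (!is.null(x$ranks)) {
    out$rank <- x$ranks$rank
    out$dist_from_start <- x$ranks$dist_from_start
  }
  em <- tibble::as_tibble(x$emissions)
  names(em) <- paste0("emit_", BASES)
  dplyr::bind_cols(out, em)
}

#' One-row summary of a Markov scorer
#'
#' @param x A `markov_scorer`.
#' @param ... Unused.
#' @return Tibble: number of states, number of positive directed
#'   transitions, start state, longest admissible path length.
#' @method glance markov_scorer
#' @export
glance.markov_scorer <- function(x, ...) {
  n_edges <- if (!is.null(x$transitions)) sum(x$transitions > 0) else NA
  longest <- if (!is.null(x$transitions)) longest_path_length(x) else NA
  tibble::tibble(n_states = nrow(x$states), n_transitions = n_edges,
                 start_state = x$start %||% NA_integer_,
                 longest_path = longest)
}

## Longest path (in states) from the start over positive transitions; the
## direction pruning makes the graph acyclic so DP terminates.
longest_path_length <- function(scorer) {
  k <- nrow(scorer$states)
  adj <- scorer$transitions > 0
  len <- rep(-Inf, k); len[scorer$start] <- 1
  ord <- order(scorer$ranks$rank, decreasing = TRUE)  # high rank first
  for (s in ord) {
    if (!is.finite(len[s])) next
    for (t in which(adj[s, ])) len[t] <- max(len[t], len[s] + 1)
  }
  max(len[is.finite(len)])
}
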