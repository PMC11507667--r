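#' Cell content similarity: LCS ratio against the ground-truth length
#'
#' The similarity of an aligned ground-truth / predicted cell pair is the
#' length of the longest common subsequence of their characters divided by
#' the length of the ground-truth string, capped at 1 so over-long
#' predictions are not rewarded.  Two empty cells are perfectly similar.
#' A substring mode (longest common contiguous run) is available for
#' sensitivity analysis.
#'
#' @param gt Ground-truth cell string.
#' @param pred Predicted cell string.
#' @param mode `"subsequence"` (default) or `"substring"`.
#' @return Ratio in `[0, 1]`.
#' @export
cell_content_similarity <- function(gt, pred, mode = c("subsequence", "substring")) {
  mode <- match.arg(mode)
  if (nchar(gt) == 0 && nchar(pred) == 0) return(1)
  a <- utf8ToInt(gt); b <- utf8ToInt(pred)
  l <- if (mode == "subsequence") lcs_length_ids(a, b) else lcsubstring_length_ids(a, b)
  min(1, l / max(1, length(a)))
}

#' Cell topology similarity: IoU of span rectangles
#'
#' Each cell's topology is its grid span rectangle expressed relative to the
#' cell's own anchor position (so that a plain 1x1 cell is `(0,0,1,1)`);
#' the similarity of an aligned pair is the IoU of the two relative
#' rectangles.  This makes the score independent of where the pair sits in
#' the alignment, which the factored alignment requires.
#'
#' @param gt_span,pred_span Integer vectors `c(row_start, row_end, col_start,
#'   col_end)` in 0-based half-open grid coordinates, relative or absolute
#'   (absolute spans must share the anchor).
#' @return IoU in `[0, 1]`.
#' @export
cell_topology_similarity <- function(gt_span, pred_span) {
  a <- bbox(gt_span[3], gt_span[1], gt_span[4], gt_span[2])
  b <- bbox(pred_span[3], pred_span[1], pred_span[4], pred_span[2])
  iou(a, b)
}

# Precompute the 4-d similarity array f[i, k, j, l] between cell (i, j) of A
# and cell (k, l) of B for the requested variant.
grits_sim_array <- function(A, B, variant) {
  RA <- grid_nrow(A); CA <- grid_ncol(A)
  RB <- grid_nrow(B); CB <- grid_ncol(B)
  arr <- array(0, dim = c(RA, RB, CA, CB))
  if (variant == "content") {
    ids_a <- lapply(A$cells, utf8ToInt)      # column-major: index (j-1)*RA + i
    ids_b <- lapply(B$cells, utf8ToInt)
    lcsm <- lcs_length_matrix(ids_a, ids_b)  # (RA*CA) x (RB*CB), column-major cells
    len_a <- matrix(nchar(A$cells), RA, CA)
    len_b <- matrix(nchar(B$cells), RB, CB)
    for (j in seq_len(CA)) for (l in seq_len(CB)) {
      rows_a <- (j - 1L) * RA + seq_len(RA)
      cols_b <- (l - 1L) * RB + seq_len(RB)
      sub <- lcsm[rows_a, cols_b, drop = FALSE]
      # symmetric normalized LCS so GriTS(A,B) mirrors GriTS(B,A)
      denom <- outer(len_a[, j], len_b[, l], `+`)
      sim <- 2 * sub / pmax(1, denom)
      sim[denom == 0] <- 1  # both empty: perfectly similar
      arr[, , j, l] <- sim
    }
  } else {
    spans_a <- grid_spans(A); spans_b <- grid_spans(B)
    rel <- function(spans, R, C) {
      # relative span rectangle per cell, cells in column-major order
      out <- vector("list", R * C)
      for (r in seq_len(R)) for (cc in seq_len(C)) {
        sp <- spans[[(r - 1L) * C + cc]]
        out[[(cc - 1L) * R + r]] <- c(sp[1] - (r - 1L), sp[2] - (r - 1L),
                                      sp[3] - (cc - 1L), sp[4] - (cc - 1L))
      }
      out
    }
    ra <- rel(spans_a, RA, CA); rb <- rel(spans_b, RB, CB)
    for (j in seq_len(CA)) for (l in seq_len(CB)) {
      for (i in seq_len(RA)) for (k in seq_len(RB)) {
        arr[i, k, j, l] <- cell_topology_similarity(ra[[(j - 1L) * RA + i]],
                                                    rb[[(l - 1L) * RB + k]])
      }
    }
  }
  arr
}

# Needleman-Wunsch style maximal alignment of two index sequences given a
# pairwise score matrix (no gap penalty).  Returns score and matched pairs.
align_dp <- function(S) {
  n <- nrow(S); m <- ncol(S)
  dp <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      dp[i + 1, j + 1] <- max(dp[i, j + 1], dp[i + 1, j], dp[i, j] + S[i, j])
    }
  }
  # traceback (prefer diagonal so maximal-score pairs are recovered)
  pairs <- matrix(integer(0), 0, 2)
  i <- n; j <- m
  while (i > 0 && j > 0) {
    if (abs(dp[i + 1, j + 1] - (dp[i, j] + S[i, j])) < 1e-12) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1; j <- j - 1
    } else if (dp[i, j + 1] >= dp[i + 1, j]) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(score = dp[n + 1, m + 1], pairs = pairs)
}

# Row-pair score matrix given a fixed column alignment (cp: matrix of
# matched (j, l) pairs); arr is the f array.
row_scores_given_cols <- function(arr, cp) {
  RA <- dim(arr)[1]; RB <- dim(arr)[2]
  S <- matrix(0, RA, RB)
  for (t in seq_len(nrow(cp))) {
    S <- S + matrix(arr[, , cp[t, 1], cp[t, 2]], RA, RB)
  }
  S
}

col_scores_given_rows <- function(arr, rp) {
  CA <- dim(arr)[3]; CB <- dim(arr)[4]
  S <- matrix(0, CA, CB)
  for (t in seq_len(nrow(rp))) {
    S <- S + matrix(arr[rp[t, 1], rp[t, 2], , ], CA, CB)
  }
  S
}

# One alternating refinement run from a given starting row alignment.
grits_refine <- function(arr, rp, passes = 3) {
  best <- list(score = -Inf, rows = rp, cols = matrix(integer(0), 0, 2))
  prev_score <- -Inf
  for (p in seq_len(passes)) {
    ca <- align_dp(col_scores_given_rows(arr, rp))
    cp <- ca$pairs
    ra <- align_dp(row_scores_given_cols(arr, cp))
    rp <- ra$pairs
    if (ra$score > best$score) best <- list(score = ra$score, rows = rp, cols = cp)
    if (abs(ra$score - prev_score) < 1e-12) break
    prev_score <- ra$score
  }
  best
}

# Starting row alignments for the alternating refinement: row-first (inner
# column DP per row pair), column-first (inner row DP per column pair), and
# deterministic restarts seeded from each single column pair.  Multiple
# restarts guard against local optima of the alternating scheme.
grits_start_points <- function(arr) {
  RA <- dim(arr)[1]; RB <- dim(arr)[2]; CA <- dim(arr)[3]; CB <- dim(arr)[4]
  starts <- list()
  S0r <- matrix(0, RA, RB)
  for (i in seq_len(RA)) for (k in seq_len(RB)) {
    S0r[i, k] <- align_dp(matrix(arr[i, k, , ], CA, CB))$score
  }
  starts[[1]] <- align_dp(S0r)$pairs
  S0c <- matrix(0, CA, CB)
  for (j in seq_len(CA)) for (l in seq_len(CB)) {
    S0c[j, l] <- align_dp(matrix(arr[, , j, l], RA, RB))$score
  }
  cp0 <- align_dp(S0c)$pairs
  starts[[2]] <- align_dp(row_scores_given_cols(arr, cp0))$pairs
  for (j in seq_len(CA)) {
    for (l in seq_len(CB)) {
      seed <- matrix(c(j, l), 1, 2)
      starts[[length(starts) + 1L]] <-
        align_dp(row_scores_given_cols(arr, seed))$pairs
    }
  }
  unique(starts)
}

#' Grid table similarity (GriTS)
#'
#' Aligns a ground-truth grid `A` and a predicted grid `B` by selecting row
#' and column subsequences that maximize the summed per-cell similarity, then
#' reports the F-score (twice the aligned similarity mass over the total cell
#' counts), precision (mass over the predicted cell count) and recall (mass
#' over the ground-truth cell count).  The alignment is found by a factored
#' heuristic: a dynamic-programming alignment over rows whose row-pair scores
#' come from a dynamic-programming alignment over columns, alternated to a
#' fixed point (at most `passes` passes) from both a row-first and a
#' column-first initialization.  On small grids the heuristic can be checked
#' against [grits_exact()].
#'
#' @param A Ground-truth [table_grid()].
#' @param B Predicted [table_grid()].
#' @param variant `"content"` (LCS cell similarity) or `"topology"` (span
#'   rectangle IoU).
#' @param passes Maximum alternating refinement passes.
#' @return Object of class `grits_result`: list with `f_score`, `precision`,
#'   `recall`, `aligned_similarity`, `variant`, and the selected `rows` /
#'   `cols` index pairs.
#' @export
grits <- function(A, B, variant = c("content", "topology"), passes = 3) {
  variant <- match.arg(variant)
  if (grid_nrow(A) == 0 || grid_ncol(A) == 0 || grid_nrow(B) == 0 || grid_ncol(B) == 0) {
    stop("grits requires non-empty grids")
  }
  arr <- grits_sim_array(A, B, variant)
  best <- NULL
  for (rp in grits_start_points(arr)) {
    r <- grits_refine(arr, rp, passes)
    if (is.null(best) || r$score > best$score) best <- r
  }
  grits_result(best, A, B, variant)
}

grits_result <- function(best, A, B, variant) {
  nA <- grid_nrow(A) * grid_ncol(A)
  nB <- grid_nrow(B) * grid_ncol(B)
  s <- best$score
  structure(list(
    f_score = 2 * s / (nA + nB),
    precision = s / nB,
    recall = s / nA,
    aligned_similarity = s,
    variant = variant,
    rows = best$rows, cols = best$cols
  ), class = "grits_result")
}

#' @export
print.grits_result <- function(x, ...) {
  cat(sprintf("GriTS[%s]  F = %.4f  P = %.4f  R = %.4f (aligned mass %.3f)\n",
              x$variant, x$f_score, x$precision, x$recall, x$aligned_similarity))
  invisible(x)
}

# enumerate all strictly increasing matchings between 1..n and 1..m
enumerate_matchings <- function(n, m) {
  out <- list()
  gen <- function(i, j, cur) {
    out[[length(out) + 1L]] <<- cur
    if (i > n || j > m) return()
    for (a in i:n) for (b in j:m) {
      gen(a + 1L, b + 1L, rbind(cur, c(a, b)))
    }
  }
  gen(1L, 1L, matrix(integer(0), 0, 2))
  out
}

#' Exhaustive-enumeration GriTS for small grids
#'
#' Enumerates every pair of row-subsequence and column-subsequence alignments
#' and maximizes the summed cell similarity exactly.  Intended as the
#' independent optimum for verifying the factored heuristic; refuses grids
#' larger than `max_dim` in any dimension.
#'
#' @inheritParams grits
#' @param max_dim Largest grid dimension accepted (default 5).
#' @return A `grits_result`, as for [grits()].
#' @export
grits_exact <- function(A, B, variant = c("content", "topology"),
                        max_dim = 5) {
  variant <- match.arg(variant)
  dims <- c(dim(A$cells), dim(B$cells))
  if (any(dims == 0)) stop("grits requires non-empty grids")
  if (any(dims > max_dim)) stop("grits_exact limited to small grids")
  arr <- grits_sim_array(A, B, variant)
  row_ms <- enumerate_matchings(dim(arr)[1], dim(arr)[2])
  col_ms <- enumerate_matchings(dim(arr)[3], dim(arr)[4])
  best <- list(score = 0, rows = row_ms[[1]], cols = col_ms[[1]])
  for (rp in row_ms) {
    if (nrow(rp) == 0) next
    CS <- col_scores_given_rows(arr, rp)
    for (cp in col_ms) {
      if (nrow(cp) == 0) next
      s <- sum(CS[cp])
      if (s > best$score + 1e-15) best <- list(score = s, rows = rp, cols = cp)
    }
  }
  grits_result(best, A, B, variant)
}

#' Align a gold table with extracted candidates by vocabulary overlap
#'
#' The vocabulary of a grid is its set of whitespace-separated tokens; a
#' candidate matches when it covers strictly more than `threshold` of the
#' gold vocabulary.  Returns the best-covering candidate or `NULL`.
#'
#' @param gold Gold [table_grid()].
#' @param candidates List of candidate [table_grid()]s.
#' @param threshold Minimum (exclusive) coverage of the gold vocabulary.
#' @return `NULL`, or a list with `index`, `overlap` and `grid`.
#' @export
align_tables_by_vocab <- function(gold, candidates, threshold = 0.4) {
  vocab <- function(g) {
    toks <- unlist(strsplit(as.vector(g$cells), "[[:space:]]+"))
    unique(toks[nzchar(toks)])
  }
  vg <- vocab(gold)
  if (length(vg) == 0 || length(candidates) == 0) return(NULL)
  ov <- vapply(candidates, function(cand) {
    length(intersect(vg, vocab(cand))) / length(vg)
  }, numeric(1))
  best <- which.max(ov)
  if (ov[best] > threshold) {
    list(index = best, overlap = ov[best], grid = candidates[[best]])
  } else NULL
}
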