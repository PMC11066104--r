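# Visit-history matching of progressive vs non-progressive subjects.
#
# A progressive subject's history is the vector of day-counts from each
# pre-diagnosis visit to the first dementia visit (ending in 0). For
# non-progressive subjects every (start visit, terminal visit) pair yields a
# candidate history re-zeroed at the chosen terminal visit. Pair costs are
# the sum of absolute differences between equal-length histories (infinite
# when no equal-length candidate exists), and pairs are chosen by a globally
# optimal assignment (Hungarian / shortest augmenting path).

#' Candidate visit histories for a non-progressive subject
#'
#' One candidate per (start index, terminal index) pair with start < terminal:
#' the vector of days from each included visit to the terminal visit,
#' strictly decreasing and ending in 0.
#'
#' @param visit_days strictly increasing integer day offsets (>= 2 visits).
#' @return list of numeric history vectors.
#' @export
enumerate_histories <- function(visit_days) {
  n <- length(visit_days)
  if (n < 2) stop("subject needs at least 2 visits to form a history")
  if (any(diff(visit_days) <= 0)) stop("visit days must be strictly increasing")
  out <- list()
  for (j in 2:n)
    for (i in 1:(j - 1))
      out[[length(out) + 1L]] <- visit_days[j] - visit_days[i:j]
  out
}

#' Progressive subject's (fixed) visit history
#'
#' Days from every visit preceding the first dementia visit to that visit,
#' with the terminal 0 appended.
#'
#' @param visit_days increasing day offsets.
#' @param diagnosis diagnoses aligned with `visit_days` (`DEM` marks dementia).
#' @return numeric history vector, or `NULL` when the subject never
#'   progresses or has no pre-diagnosis visit.
#' @export
progressive_history <- function(visit_days, diagnosis) {
  pos <- which(diagnosis == "DEM")
  if (!length(pos)) return(NULL)
  t_pos <- visit_days[min(pos)]
  before <- visit_days[visit_days < t_pos]
  if (!length(before)) return(NULL)
  c(t_pos - before, 0)
}

#' Cost between two equal-length histories
#'
#' Sum of absolute pairwise differences between the day vectors.
#'
#' @param h1,h2 histories of equal length.
#' @return nonnegative cost in days.
#' @export
history_cost <- function(h1, h2) {
  if (length(h1) != length(h2))
    stop("histories must have equal length (got ", length(h1), " and ",
         length(h2), ")")
  sum(abs(h1 - h2))
}

#' Best achievable cost between a progressive history and a candidate set
#'
#' @param h_prog the progressive subject's history.
#' @param candidates list of candidate histories (see
#'   [enumerate_histories()]).
#' @return minimum [history_cost()] over equal-length candidates, with the
#'   minimizing candidate index in attribute `"which"`; `Inf` when no
#'   candidate matches in length.
#' @export
best_pair_cost <- function(h_prog, candidates) {
  ok <- which(lengths(candidates) == length(h_prog))
  if (!length(ok)) return(Inf)
  costs <- vapply(ok, function(i) history_cost(h_prog, candidates[[i]]), 0)
  best <- which.min(costs)
  structure(costs[best], which = ok[best])
}

# Shortest-augmenting-path solver for the rectangular assignment problem.
# `Inf` entries are forbidden edges. Rows that cannot be matched through
# finite-cost paths are left unassigned. Returns an integer vector: for each
# row, the assigned column or NA.
#' @noRd
solve_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  stopifnot(nr <= nc)
  # Potential-based shortest augmenting paths with a virtual column 0.
  # a[i, j] with 1-based rows/cols; p[j] = row matched to column j (0 = none).
  u <- numeric(nr + 1)
  v <- numeric(nc + 1)
  p <- integer(nc + 1)
  for (r in seq_len(nr)) {
    u_bak <- u; v_bak <- v; p_bak <- p     # rollback on unmatchable rows
    p[1] <- r                              # column 0 holds the new row
    j0 <- 0L
    minv <- rep(Inf, nc)
    way <- integer(nc)
    used <- logical(nc + 1)
    failed <- FALSE
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- NA_integer_
      for (j in seq_len(nc)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0 + 0] - v[j + 1]
        if (is.nan(cur)) cur <- Inf
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      if (!is.finite(delta)) { failed <- TRUE; break }
      for (j in 0:nc) {
        if (used[j + 1]) {
          if (p[j + 1] > 0) u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    if (failed) { u <- u_bak; v <- v_bak; p <- p_bak; next }
    repeat {                               # augment along the stored path
      j1 <- way[j0]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- rep(NA_integer_, nr)
  for (j in seq_len(nc)) if (p[j + 1] > 0) out[p[j + 1]] <- j
  out
}

#' Globally optimal matching from a pair-cost matrix
#'
#' Solves the rectangular assignment problem minimizing total cost; `Inf`
#' entries are never selected. When some rows admit no finite-cost partner, a
#' maximal finite-cost partial matching is returned and the unmatched rows
#' are reported.
#'
#' @param cost numeric matrix: rows = progressive subjects, columns =
#'   non-progressive subjects, entries = [best_pair_cost()] values (may be
#'   `Inf`).
#' @return object of class `match_result`: data.frame `pairs`
#'   (`progressive`, `nonprogressive`, `cost`, using dimnames when present),
#'   `total_cost`, `unmatched` (row ids).
#' @export
assign_matches <- function(cost) {
  cost <- as.matrix(cost)
  transposed <- nrow(cost) > ncol(cost)
  m <- if (transposed) t(cost) else cost
  assignment <- solve_assignment(m)
  rows <- which(!is.na(assignment))
  cols <- assignment[rows]
  if (transposed) { tmp <- rows; rows <- cols; cols <- tmp }
  rn <- rownames(cost) %||% as.character(seq_len(nrow(cost)))
  cn <- colnames(cost) %||% as.character(seq_len(ncol(cost)))
  ord <- order(rows)
  rows <- rows[ord]; cols <- cols[ord]
  pairs <- data.frame(progressive = rn[rows], nonprogressive = cn[cols],
                      cost = cost[cbind(rows, cols)],
                      stringsAsFactors = FALSE)
  unmatched <- setdiff(seq_len(nrow(cost)), rows)
  if (length(unmatched))
    message(length(unmatched),
            " progressive subject(s) had no finite-cost match and were excluded")
  structure(list(pairs = pairs, total_cost = sum(pairs$cost),
                 unmatched = rn[unmatched]),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs, total cost %g, %d unmatched\n",
              nrow(x$pairs), x$total_cost, length(x$unmatched)))
  invisible(x)
}

#' Match progressive against non-progressive subjects in a visit table
#'
#' Builds the pair-cost matrix from visit histories (progressive rows,
#' non-progressive columns, excluding ambiguous trajectories) and solves the
#' optimal assignment. The same non-progressive subject may offer different
#' candidate histories to different progressive subjects; each matrix cell
#' stores that pair's own optimum.
#'
#' @param visits data.frame with `subject_id`, `visit_date`, `diagnosis`
#'   (as produced by [generate_visit_table()]).
#' @return a `match_result` (see [assign_matches()]), with the chosen history
#'   variant per pair in `pairs$history_length`.
#' @export
match_visit_histories <- function(visits) {
  split_v <- split(visits, visits$subject_id)
  cls <- vapply(split_v, function(d) classify_trajectory(d$diagnosis), "")
  prog <- split_v[cls == "progressive"]
  nonprog <- split_v[cls %in% c("stable", "improving")]
  prog_h <- lapply(prog, function(d) progressive_history(d$visit_date, d$diagnosis))
  prog_h <- Filter(Negate(is.null), prog_h)
  nonprog <- Filter(function(d) nrow(d) >= 2, nonprog)
  if (!length(prog_h) || !length(nonprog))
    stop("need at least one progressive and one non-progressive subject")
  cand <- lapply(nonprog, function(d) enumerate_histories(d$visit_date))
  cost <- matrix(Inf, length(prog_h), length(cand),
                 dimnames = list(names(prog_h), names(cand)))
  for (i in seq_along(prog_h))
    for (j in seq_along(cand))
      cost[i, j] <- best_pair_cost(prog_h[[i]], cand[[j]])
  res <- assign_matches(cost)
  res$pairs$history_length <- lengths(prog_h[res$pairs$progressive])
  res
}

#' Classify a diagnostic trajectory
#'
#' `stable`: MCI throughout; `improving`: MCI then CN with no dementia;
#' `progressive`: MCI visits followed by dementia, never reverting;
#' `ambiguous`: anything else (excluded from the longitudinal analyses).
#'
#' @param diagnosis character vector of visit diagnoses in time order.
#' @return one of `"stable"`, `"improving"`, `"progressive"`, `"ambiguous"`.
#' @export
classify_trajectory <- function(diagnosis) {
  if (all(diagnosis == "MCI")) return("stable")
  if (!any(diagnosis == "MCI")) return("ambiguous")
  first_dem <- match("DEM", diagnosis)
  if (!is.na(first_dem)) {
    if (all(diagnosis[first_dem:length(diagnosis)] == "DEM") &&
        all(diagnosis[seq_len(first_dem - 1)] == "MCI"))
      return("progressive")
    return("ambiguous")
  }
  first_cn <- match("CN", diagnosis)
  if (all(diagnosis[first_cn:length(diagnosis)] == "CN") &&
      all(diagnosis[seq_len(first_cn - 1)] == "MCI"))
    return("improving")
  "ambiguous"
}
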