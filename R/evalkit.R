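# Evaluation kit: score maps -> discrete detections -> precision/recall/F_beta.

#' Extract peak detections from a score map
#'
#' Local maxima at or above `threshold`, non-maximum suppressed within
#' `min_distance`; ties broken by (score desc, y asc, x asc).
#'
#' @param score_map numeric matrix of per-pixel scores in \[0,1\]
#' @param threshold detection threshold in (0,1)
#' @param min_distance suppression radius in pixels
#' @param t frame index attached to the detections (0-based)
#' @return data.frame (`t, x, y, score`), 0-based pixel coordinates
#' @export
extract_peaks <- function(score_map, threshold, min_distance = 8, t = 0L) {
  stopifnot(is.matrix(score_map), threshold > 0, threshold < 1)
  H <- nrow(score_map); W <- ncol(score_map)
  emptyd <- data.frame(t = integer(0), x = numeric(0), y = numeric(0),
                       score = numeric(0))
  cand <- which(score_map >= threshold)
  if (!length(cand)) return(emptyd)
  # local maximum over the 8-neighborhood (plateaus count once via strict >
  # on earlier neighbors and >= on later ones handled by the NMS tie-break)
  pad <- matrix(-Inf, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- score_map
  is_max <- rep(TRUE, length(cand))
  ci <- (cand - 1L) %% H + 1L
  cj <- (cand - 1L) %/% H + 1L
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & score_map[cand] >= pad[cbind(ci + 1L + di, cj + 1L + dj)]
  }
  cand <- cand[is_max]
  if (!length(cand)) return(emptyd)
  ci <- (cand - 1L) %% H + 1L
  cj <- (cand - 1L) %/% H + 1L
  d <- data.frame(t = as.integer(t), x = cj - 1L, y = ci - 1L,
                  score = score_map[cand])
  d <- d[order(-d$score, d$y, d$x), , drop = FALSE]
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    kept <- d[keep, , drop = FALSE]
    dist2 <- (kept$x - d$x[i])^2 + (kept$y - d$y[i])^2
    keep[i] <- all(dist2 >= min_distance^2)
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group per-frame detections into event detections
#'
#' Single-linkage clustering of detections that are within `dist_tol` pixels
#' and `time_link` frames of each other; each cluster is represented by its
#' highest-scoring member. This collapses the per-frame peaks an event
#' produces on its several labeled frames into one detection before matching.
#'
#' @param detections data.frame from [extract_peaks()] over several frames
#' @param dist_tol spatial linkage radius (px)
#' @param time_link temporal linkage (frames)
#' @return grouped detections data.frame
#' @export
group_detections <- function(detections, dist_tol = 10, time_link = 2) {
  n <- nrow(detections)
  if (n <= 1L) return(detections)
  ord <- order(detections$t)
  t <- detections$t[ord]; x <- detections$x[ord]; y <- detections$y[ord]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # time-sorted sweep: only candidate pairs within time_link need a look
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && t[j] - t[i] <= time_link) {
      if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= dist_tol^2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
      j <- j + 1L
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  keep <- vapply(split(seq_len(n), roots), function(members)
    members[which.max(detections$score[ord[members]])], integer(1))
  out <- detections[sort(ord[keep]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedily match detections to ground-truth events
#'
#' Matches in ascending spatio-temporal distance: a detection may match a
#' positive event if its spatial distance to the event center is within
#' `dist_tol` and its frame is within `time_tol` of the nearest labeled frame
#' (the last five frames of the event). Each detection and each event matches
#' at most once.
#'
#' @param detections data.frame as from [extract_peaks()]
#' @param events event table (only `polarity == "positive"` rows are targets)
#' @param dist_tol spatial tolerance in pixels
#' @param time_tol temporal tolerance in frames
#' @return object of class `match_result`: lists of `true_positives`,
#'   `false_positives` (detections), `false_negatives` (events), plus counts
#' @export
match_events <- function(detections, events, dist_tol = 10, time_tol = 2) {
  stopifnot(dist_tol >= 0, time_tol >= 0)
  pos <- events[events$polarity == "positive", , drop = FALSE]
  nd <- nrow(detections); ne <- nrow(pos)
  pairs <- NULL
  if (nd > 0 && ne > 0) {
    sdm <- sqrt(outer(detections$x, pos$x, "-")^2 +
                  outer(detections$y, pos$y, "-")^2)
    lab0 <- pmax(pos$t_start, pos$t_end - 4L)            # labeled frames
    dtm <- pmax(outer(-detections$t, lab0, "+"),         # lab0 - t
                outer(detections$t, -pos$t_end, "+"),    # t - t_end
                0)
    elig <- sdm <= dist_tol & dtm <= time_tol
    if (any(elig)) {
      idx <- which(elig, arr.ind = TRUE)
      pairs <- cbind(idx[, 1], idx[, 2], sdm[elig] + dtm[elig])
    }
  }
  matched_d <- logical(nd); matched_e <- logical(ne)
  if (!is.null(pairs)) {
    # greedy pass in ascending spatio-temporal distance ...
    d_of_e <- integer(ne); e_of_d <- integer(nd)
    pairs <- pairs[order(pairs[, 3]), , drop = FALSE]
    elig <- lapply(seq_len(nd), function(i)
      pairs[pairs[, 1] == i, 2])
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (e_of_d[i] == 0L && d_of_e[j] == 0L) {
        e_of_d[i] <- j; d_of_e[j] <- i
      }
    }
    # ... then augmenting-path repair so the TP count is the maximum
    # bipartite matching on the tolerance graph (greedy alone can strand a
    # matchable detection)
    augment <- function(i, seen) {
      for (j in elig[[i]]) {
        if (seen[j]) next
        seen[j] <- TRUE
        if (d_of_e[j] == 0L) {
          d_of_e[j] <<- i; e_of_d[i] <<- j
          return(TRUE)
        }
        other <- d_of_e[j]
        res <- augment(other, seen)
        if (res) {
          d_of_e[j] <<- i; e_of_d[i] <<- j
          return(TRUE)
        }
      }
      FALSE
    }
    for (i in seq_len(nd)) {
      if (e_of_d[i] == 0L && length(elig[[i]]))
        augment(i, rep(FALSE, ne))
    }
    matched_d <- e_of_d != 0L
    matched_e <- d_of_e != 0L
  }
  structure(list(
    true_positives = detections[matched_d, , drop = FALSE],
    false_positives = detections[!matched_d, , drop = FALSE],
    false_negatives = pos[!matched_e, , drop = FALSE],
    n_tp = sum(matched_d), n_fp = sum(!matched_d), n_fn = sum(!matched_e),
    dist_tol = dist_tol, time_tol = time_tol), class = "match_result")
}

precision_recall <- function(match) {
  tp <- match$n_tp; fp <- match$n_fp; fn <- match$n_fn
  p <- if (tp + fp == 0) { if (tp + fn == 0) 1 else 0 } else tp / (tp + fp)
  r <- if (tp + fn == 0) 1 else tp / (tp + fn)
  c(precision = p, recall = r)
}

#' The F_beta score
#'
#' `F_beta = (1 + beta^2) P R / (beta^2 P + R)`, defined as 0 when
#' `P = R = 0`. With the default `beta = 0.1` the metric prioritizes
#' precision over recall, penalizing false triggers.
#'
#' @param precision,recall values in \[0,1\]
#' @param beta precision/recall weight
#' @return the F_beta value
#' @export
fbeta <- function(precision, recall, beta = 0.1) {
  stopifnot(all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  den <- beta^2 * precision + recall
  ifelse(den > 0, (1 + beta^2) * precision * recall / den, 0)
}

#' Optimize the detection threshold for F_beta
#'
#' Scores every grid threshold on the provided (validation) score maps and
#' returns the one maximizing F_beta; ties go to the lowest threshold.
#' Precision and recall are reported at that threshold.
#'
#' @param score_maps list of score matrices, one per frame (0-based frame t =
#'   position - 1), or a list of `(t, map)` pairs via names
#' @param events ground-truth event table (needs >= 1 positive event)
#' @param beta F_beta weight
#' @param grid candidate thresholds in (0,1)
#' @param dist_tol,time_tol,min_distance matching geometry
#' @param frame_ts optional integer vector of 0-based frame indices for
#'   `score_maps` (defaults to `seq_along(score_maps) - 1`)
#' @param group collapse per-frame detections of one event into a single
#'   detection via [group_detections()] before matching (default TRUE)
#' @return list(`threshold`, `scores` = list(precision, recall, f_beta, beta,
#'   threshold), `grid_scores` data.frame)
#' @export
optimize_threshold <- function(score_maps, events, beta = 0.1,
                               grid = seq(0.01, 0.99, by = 0.01),
                               dist_tol = 10, time_tol = 2, min_distance = 8,
                               frame_ts = NULL, group = TRUE) {
  if (!any(events$polarity == "positive"))
    stop("optimize_threshold: no positive events in the validation set")
  stopifnot(all(grid > 0 & grid < 1))
  if (is.null(frame_ts)) frame_ts <- seq_along(score_maps) - 1L
  # extract once at the lowest threshold; group once (the representative of a
  # group carries its max score), then re-threshold the grouped detections
  base <- do.call(rbind, lapply(seq_along(score_maps), function(i)
    extract_peaks(score_maps[[i]], min(grid), min_distance, t = frame_ts[i])))
  if (group && !is.null(base)) base <- group_detections(base, dist_tol, time_tol)
  res <- data.frame(threshold = grid, precision = NA_real_, recall = NA_real_,
                    f_beta = NA_real_)
  for (g in seq_along(grid)) {
    det <- base[base$score >= grid[g], , drop = FALSE]
    m <- match_events(det, events, dist_tol, time_tol)
    pr <- precision_recall(m)
    res$precision[g] <- pr["precision"]; res$recall[g] <- pr["recall"]
    res$f_beta[g] <- fbeta(pr["precision"], pr["recall"], beta)
  }
  best <- which.max(res$f_beta)           # which.max returns the first (lowest)
  list(threshold = grid[best],
       scores = list(precision = res$precision[best], recall = res$recall[best],
                     f_beta = res$f_beta[best], beta = beta,
                     threshold = grid[best]),
       grid_scores = res)
}

#' Select the best model among seeded runs
#'
#' @param runs list of `list(detector = ..., scores = ...)` entries where
#'   `scores$f_beta` is the validation F_beta
#' @return the entry with the highest F_beta (ties: lowest index)
#' @export
select_best_model <- function(runs) {
  if (!length(runs)) stop("select_best_model: no runs")
  fb <- vapply(runs, function(r) r$scores$f_beta, numeric(1))
  runs[[which.max(fb)]]
}
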