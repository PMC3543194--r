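# Window scanning, rank statistics, ROC areas and peak matching.

#' Best-scoring window of a sequence on either strand
#'
#' Scores every l-length window of the forward strand and of the reverse
#' complement and returns the best hit.  Ties are broken by smaller start
#' coordinate, then by the forward strand.  Windows containing non-ACGT
#' characters are skipped (their count is reported); a sequence shorter
#' than `l` is an error.
#'
#' @param seq A single DNA sequence (character scalar).
#' @param scorer A fitted scorer (see [site_scores()]).
#' @param l Window length; defaults to the scorer's site length.
#' @param seq_id Identifier stored in the hit.
#' @return A one-row `data.frame` with columns `seq_id`, `start` (0-based),
#'   `end` (half-open), `strand`, `score`, `n_skipped`.
#' @export
score_sequence <- function(seq, scorer, l = scorer_length(scorer),
                           seq_id = "seq") {
  stopifnot(length(seq) == 1L)
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < l) {
    stop(sprintf("sequence '%s' is shorter (%d) than l = %d", seq_id, L, l),
         call. = FALSE)
  }
  starts <- seq_len(L - l + 1L)  # 1-based window starts
  fwd <- substring(seq, starts, starts + l - 1L)
  rc <- reverse_complement(seq)
  rev_win <- substring(rc, starts, starts + l - 1L)
  # reverse-strand window j (1-based in the revcomp) covers forward
  # 0-based interval [L - j - l + 1, L - j + 1)
  cand <- data.frame(
    start = c(starts - 1L, L - starts - l + 1L),
    strand = rep(c("+", "-"), each = length(starts)),
    site = c(fwd, rev_win),
    stringsAsFactors = FALSE
  )
  ok <- !grepl("[^ACGT]", cand$site)
  n_skipped <- sum(!ok) / 2L  # each invalid window appears on both strands
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop(sprintf("sequence '%s' has no ACGT-only window of length %d",
                 seq_id, l), call. = FALSE)
  }
  cand$score <- site_scores(scorer, cand$site)
  best <- order(-cand$score, cand$start, cand$strand)[1L]
  data.frame(seq_id = seq_id, start = cand$start[best],
             end = cand$start[best] + l, strand = cand$strand[best],
             score = cand$score[best], n_skipped = n_skipped,
             stringsAsFactors = FALSE)
}

#' Best-window scores for a collection of sequences
#'
#' Applies [score_sequence()] to each sequence and returns the vector of
#' best scores.  Sequences of length exactly `l` are scored directly on
#' both strands.
#'
#' @param seqs Character vector of sequences (lengths >= l).
#' @inheritParams score_sequence
#' @return Numeric vector of best scores, one per sequence.
#' @export
score_sequences <- function(seqs, scorer, l = scorer_length(scorer)) {
  seqs <- toupper(as.character(seqs))
  lens <- nchar(seqs)
  out <- numeric(length(seqs))
  exact <- lens == l & !grepl("[^ACGT]", seqs)
  if (any(exact)) {
    out[exact] <- score_sites_bidir(scorer, seqs[exact])
  }
  for (i in which(!exact)) {
    out[i] <- score_sequence(seqs[i], scorer, l = l)$score
  }
  out
}

#' Rank of a test score among negative scores
#'
#' The rank is `1 + |{s in N_test : Score(s) >= Score(t)}|`, i.e. ties
#' count against the test site.
#'
#' @param t_score Score of the test site (scalar or vector).
#' @param neg_scores Scores of the test negatives.
#' @return Integer rank(s) in `1 .. length(neg_scores) + 1`.
#' @export
rank_among_negatives <- function(t_score, neg_scores) {
  stopifnot(length(neg_scores) > 0L)
  vapply(t_score, function(s) 1L + sum(neg_scores >= s), integer(1))
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' `(#{pos > neg} + 0.5 #{pos = neg}) / (n_pos * n_neg)`; ties get half
#' credit.
#'
#' @param pos_scores Scores of positives.
#' @param neg_scores Scores of negatives.
#' @return AUC in [0, 1].
#' @export
auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores)
  nn <- length(neg_scores)
  stopifnot(np > 0L, nn > 0L)
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# empirical ROC vertices: thresholds at distinct scores, (0,0) prepended
roc_points <- function(pos_scores, neg_scores) {
  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(s) mean(pos_scores >= s), numeric(1)))
  fpr <- c(0, vapply(thr, function(s) mean(neg_scores >= s), numeric(1)))
  list(fpr = fpr, tpr = tpr)
}

#' Partial AUC at a false-positive-rate cap
#'
#' Area under the empirical ROC curve restricted to FPR in
#' `[0, fpr_max]`, rescaled by `1 / fpr_max` to lie in [0, 1].  The curve
#' is piecewise linear between ROC vertices (thresholds at distinct
#' scores), so tied scores contribute diagonal segments.
#'
#' @inheritParams auc
#' @param fpr_max Upper FPR bound, in (0, 1]; the default 0.01 mirrors
#'   genome-scale scanning where only a tiny false-positive budget is
#'   tolerable.
#' @return Scaled partial AUC in [0, 1].
#' @export
partial_auc <- function(pos_scores, neg_scores, fpr_max = 0.01) {
  stopifnot(fpr_max > 0, fpr_max <= 1)
  rp <- roc_points(pos_scores, neg_scores)
  area <- 0
  for (k in seq_len(length(rp$fpr) - 1L)) {
    x0 <- rp$fpr[k]; x1 <- rp$fpr[k + 1L]
    y0 <- rp$tpr[k]; y1 <- rp$tpr[k + 1L]
    if (x0 >= fpr_max) break
    if (x1 <= fpr_max) {
      area <- area + (x1 - x0) * (y0 + y1) / 2
    } else {
      yc <- y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0)
      area <- area + (fpr_max - x0) * (y0 + yc) / 2
      break
    }
  }
  area / fpr_max
}

#' Match predicted hits to peak intervals
#'
#' A hit is a true positive iff some peak on the same reference fully
#' contains its `[start, end)` interval; a peak is recalled iff it fully
#' contains some hit.  All coordinates are 0-based half-open.
#'
#' @param hits `data.frame` with columns `seq_id`, `start`, `end`.
#' @param peaks `data.frame` with columns `chrom`, `start`, `end`.
#' @return List with logical vectors `hit_tp` (per hit) and
#'   `peak_recalled` (per peak).
#' @export
match_peaks <- function(hits, peaks) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(hits)),
            all(c("chrom", "start", "end") %in% names(peaks)))
  if (any(peaks$start >= peaks$end) || any(hits$start >= hits$end)) {
    stop("malformed intervals: start must be < end", call. = FALSE)
  }
  hit_tp <- logical(nrow(hits))
  peak_recalled <- logical(nrow(peaks))
  for (i in seq_len(nrow(hits))) {
    contains <- peaks$chrom == hits$seq_id[i] &
      peaks$start <= hits$start[i] & peaks$end >= hits$end[i]
    if (any(contains)) {
      hit_tp[i] <- TRUE
      peak_recalled[contains] <- TRUE
    }
  }
  list(hit_tp = hit_tp, peak_recalled = peak_recalled)
}
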