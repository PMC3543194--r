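# Positional nucleotide/pair frequencies, first-order transition
# probabilities and information content.

#' Estimate a positional frequency model from aligned sites
#'
#' Counts nucleotides per position, nucleotide pairs for adjacent and gap-1
#' position pairs, and position-specific transitions, and converts counts to
#' probabilities with an additive pseudocount: `f_i(u) = (count + alpha) /
#' (n + 4 alpha)` for mono frequencies, denominator `n + 16 alpha` for pair
#' frequencies, and `(count(uv at i) + alpha) / (count(u at i) + 4 alpha)`
#' for the positional transitions `f_i(v|u)`.
#'
#' The default pseudocount `alpha = 1` keeps every probability strictly
#' positive so log-based scores stay finite; `alpha = 0` gives the raw
#' maximum-likelihood estimates.
#'
#' @param sites Character vector of equal-length sites or a [site_set()].
#' @param alpha Pseudocount, `>= 0`.
#' @return An object of class `freq_model` with elements `l`, `n`, `alpha`,
#'   `mono` (4 x l probability matrix, rows A,C,G,T), `mono_counts`,
#'   `adj` and `gap` (4 x 4 x npair probability arrays, first index = left
#'   base), and `pos_trans` (4 x 4 x (l-1), `pos_trans[u, v, i]` =
#'   `f_i(v|u)`).
#' @export
estimate_frequencies <- function(sites, alpha = 1) {
  stopifnot(length(alpha) == 1L, alpha >= 0)
  sites <- as_site_chr(sites)
  codes <- site_code_matrix(sites)
  n <- nrow(codes)
  l <- ncol(codes)
  if (l < 2L) stop("sites must have length >= 2", call. = FALSE)

  mono_counts <- vapply(seq_len(l), function(i) {
    tabulate(codes[, i], nbins = 4L)
  }, numeric(4))
  dimnames(mono_counts) <- list(.BASES, seq_len(l))
  mono <- (mono_counts + alpha) / (n + 4 * alpha)

  pair_counts <- function(gap) {
    npair <- l - gap
    arr <- array(0, dim = c(4L, 4L, npair),
                 dimnames = list(.BASES, .BASES, seq_len(npair)))
    for (i in seq_len(npair)) {
      pc <- 4L * (codes[, i] - 1L) + codes[, i + gap]
      tab <- tabulate(pc, nbins = 16L)
      arr[, , i] <- matrix(tab, 4L, 4L, byrow = TRUE)
    }
    arr
  }
  adj_counts <- pair_counts(1L)
  adj <- (adj_counts + alpha) / (n + 16 * alpha)
  gap_arr <- NULL
  if (l >= 3L) {
    gap_arr <- (pair_counts(2L) + alpha) / (n + 16 * alpha)
  }

  pos_trans <- array(0, dim = c(4L, 4L, l - 1L),
                     dimnames = list(.BASES, .BASES, seq_len(l - 1L)))
  for (i in seq_len(l - 1L)) {
    pos_trans[, , i] <- (adj_counts[, , i] + alpha) /
      (mono_counts[, i] + 4 * alpha)
  }

  structure(
    list(l = l, n = n, alpha = alpha,
         mono = mono, mono_counts = mono_counts,
         adj = adj, gap = gap_arr, pos_trans = pos_trans),
    class = "freq_model"
  )
}

#' @export
print.freq_model <- function(x, ...) {
  cat(sprintf("freq_model: l = %d, n = %d sites, alpha = %g\n",
              x$l, x$n, x$alpha))
  invisible(x)
}

#' Estimate background transition probabilities from sequences
#'
#' Pools dinucleotide counts over all input sequences (given strand only)
#' and returns the first-order background transition matrix `f(v|u)`
#' together with the pooled mononucleotide distribution.  Dinucleotides
#' containing non-ACGT characters are skipped and counted.
#'
#' @param seqs Character vector of DNA sequences (any lengths >= 2).
#' @param alpha Pseudocount.
#' @return Object of class `background_model`: `trans` (4 x 4, rows `u`
#'   summing to 1), `init` (length-4 mononucleotide distribution),
#'   `n_dinuc` used, `n_skipped` invalid dinucleotides, `alpha`.
#' @export
estimate_background <- function(seqs, alpha = 1) {
  stopifnot(length(alpha) == 1L, alpha >= 0)
  seqs <- toupper(as.character(seqs))
  counts <- matrix(0, 4L, 4L, dimnames = list(.BASES, .BASES))
  mono <- numeric(4L)
  skipped <- 0L
  for (s in seqs) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    code <- match(ch, .BASES)
    mono_tab <- tabulate(code[!is.na(code)], nbins = 4L)
    mono <- mono + mono_tab
    if (length(code) < 2L) next
    a <- code[-length(code)]
    b <- code[-1L]
    ok <- !is.na(a) & !is.na(b)
    skipped <- skipped + sum(!ok)
    if (any(ok)) {
      tab <- tabulate(4L * (a[ok] - 1L) + b[ok], nbins = 16L)
      counts <- counts + matrix(tab, 4L, 4L, byrow = TRUE)
    }
  }
  if (sum(counts) == 0) stop("no valid dinucleotides in input", call. = FALSE)
  trans <- (counts + alpha) / (rowSums(counts) + 4 * alpha)
  init <- if (sum(mono) > 0) {
    (mono + alpha) / (sum(mono) + 4 * alpha)
  } else {
    rep(0.25, 4L)
  }
  names(init) <- .BASES
  structure(
    list(trans = trans, init = init, n_dinuc = sum(counts),
         n_skipped = skipped, alpha = alpha),
    class = "background_model"
  )
}

#' Information content of a frequency model
#'
#' Per-position information content `IC_i = 2 + sum_u f_i(u) log2 f_i(u)`
#' (bits; 0 for a uniform column, 2 for a degenerate one) and per-pair
#' information content `IC_{i,j} = 4 + sum_{u,v} f_{i,j}(u,v) log2
#' f_{i,j}(u,v)` for adjacent and gap-1 pairs.  The convention
#' `0 * log2(0) = 0` applies.
#'
#' @param fm A `freq_model` from [estimate_frequencies()].
#' @return Object of class `ic_profile`: `mono` (length l), `adj`
#'   (length l-1), `gap` (length l-2, NULL when l = 2).
#' @export
information_content <- function(fm) {
  stopifnot(inherits(fm, "freq_model"))
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  ic_mono <- 2 + colSums(plogp(fm$mono))
  ic_pair <- function(arr) {
    if (is.null(arr)) return(NULL)
    4 + apply(plogp(arr), 3L, sum)
  }
  structure(
    list(mono = pmin(pmax(ic_mono, 0), 2),
         adj = pmin(pmax(ic_pair(fm$adj), 0), 4),
         gap = if (is.null(fm$gap)) NULL else
           pmin(pmax(ic_pair(fm$gap), 0), 4)),
    class = "ic_profile"
  )
}

#' Information-content weights from training sites
#'
#' Convenience wrapper: estimates frequencies (pseudocount `alpha`) and
#' returns the information profile used as embedding weights.  Intended to
#' be computed on training positives only.
#'
#' @inheritParams estimate_frequencies
#' @return An `ic_profile`.
#' @export
ic_weights <- function(sites, alpha = 1) {
  information_content(estimate_frequencies(sites, alpha = alpha))
}

#' Write a position frequency matrix in JASPAR-like text format
#'
#' Writes the mononucleotide count matrix as four rows `A [ ... ]` ...
#' `T [ ... ]` preceded by a `>name` header line.
#'
#' @param fm A `freq_model`.
#' @param path Output file path.
#' @param name Motif name for the header.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(fm, path, name = "motif") {
  stopifnot(inherits(fm, "freq_model"))
  lines <- c(
    paste0(">", name),
    vapply(seq_len(4L), function(u) {
      sprintf("%s  [ %s ]", .BASES[u],
              paste(format(fm$mono_counts[u, ], trim = TRUE), collapse = " "))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
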