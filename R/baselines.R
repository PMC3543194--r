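# PSSM and ULPB baseline scorers.

#' Fit a position-specific scoring matrix scorer
#'
#' Scores an l-mer `s` by the sum of per-position log2 probabilities,
#' `sum_i log2 f_i(s_i)`.  No background model and no pair terms are used.
#'
#' @param sites Training sites (character vector or [site_set()]).
#' @param alpha Pseudocount passed to [estimate_frequencies()]; must be
#'   positive unless every observed probability is nonzero, since a zero
#'   probability would make scores infinite.
#' @return Object of class `c("pssm_scorer", "tfbs_scorer")` with the
#'   4 x l `log_mono` matrix and `l`.
#' @export
pssm_fit <- function(sites, alpha = 1) {
  fm <- estimate_frequencies(sites, alpha = alpha)
  pssm_from_model(fm)
}

#' PSSM scorer from an existing frequency model
#'
#' @param fm A `freq_model`.
#' @return A `pssm_scorer`.
#' @export
pssm_from_model <- function(fm) {
  stopifnot(inherits(fm, "freq_model"))
  # zero probabilities are tolerated in the matrix; scoring errors only if
  # a scored word actually touches one (log2(0) = -Inf is never returned)
  structure(
    list(log_mono = log2(fm$mono), l = fm$l, alpha = fm$alpha),
    class = c("pssm_scorer", "tfbs_scorer")
  )
}

#' @export
site_scores.pssm_scorer <- function(scorer, sites) {
  codes <- site_code_matrix(as_site_chr(sites), scorer$l)
  l <- scorer$l
  out <- numeric(nrow(codes))
  for (i in seq_len(l)) {
    out <- out + scorer$log_mono[cbind(codes[, i], i)]
  }
  if (any(!is.finite(out))) {
    stop("zero probability encountered while scoring; refit with a positive pseudocount",
         call. = FALSE)
  }
  unname(out)
}

#' Fit an ungapped-likelihood-under-positional-background (ULPB) scorer
#'
#' Models a binding site by a position-specific first-order Markov chain
#' and the genomic background by a homogeneous first-order chain, and
#' scores an l-mer `s` by the approximate log-likelihood ratio
#' `log2 f_1(s_1) + sum_i log2 [ f_i(s_{i+1}|s_i) / f(s_{i+1}|s_i) ]`.
#' The first term carries no background correction.
#'
#' @inheritParams pssm_fit
#' @param background A `background_model` from [estimate_background()]
#'   fitted on the sequence collection being scanned (or any suitable
#'   background sample).
#' @return Object of class `c("ulpb_scorer", "tfbs_scorer")` with
#'   `log_f1` (length 4), `log_ratio` (4 x 4 x (l-1) array of positional
#'   minus background log transition probabilities) and `l`.
#' @export
ulpb_fit <- function(sites, background, alpha = 1) {
  fm <- estimate_frequencies(sites, alpha = alpha)
  ulpb_from_model(fm, background)
}

#' ULPB scorer from existing models
#'
#' @param fm A `freq_model`.
#' @inheritParams ulpb_fit
#' @return A `ulpb_scorer`.
#' @export
ulpb_from_model <- function(fm, background) {
  stopifnot(inherits(fm, "freq_model"),
            inherits(background, "background_model"))
  if (fm$l < 2L) stop("ULPB requires l >= 2", call. = FALSE)
  if (any(background$trans == 0)) {
    stop("background transitions contain zeros; use a positive pseudocount",
         call. = FALSE)
  }
  log_ratio <- log2(fm$pos_trans) -
    rep(log2(background$trans), fm$l - 1L)
  dim(log_ratio) <- dim(fm$pos_trans)
  structure(
    list(log_f1 = log2(fm$mono[, 1L]), log_ratio = log_ratio, l = fm$l,
         alpha = fm$alpha),
    class = c("ulpb_scorer", "tfbs_scorer")
  )
}

#' @export
site_scores.ulpb_scorer <- function(scorer, sites) {
  codes <- site_code_matrix(as_site_chr(sites), scorer$l)
  l <- scorer$l
  out <- scorer$log_f1[codes[, 1L]]
  for (i in seq_len(l - 1L)) {
    out <- out + scorer$log_ratio[cbind(codes[, i], codes[, i + 1L], i)]
  }
  if (any(!is.finite(out))) {
    stop("zero probability encountered while scoring; refit with a positive pseudocount",
         call. = FALSE)
  }
  unname(out)
}
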