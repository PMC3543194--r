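# Synthetic data: first-order Markov backgrounds, PWM-planted motifs and
# two-subtype motifs with recorded ground truth.

#' Default background transition model
#'
#' Uniform initial distribution with mildly non-uniform first-order
#' transitions (each base slightly favors repeating itself), so that
#' likelihood-ratio scoring against the background is non-trivial while
#' the stationary composition stays close to uniform.
#'
#' @return A `background_model`.
#' @export
default_background <- function() {
  trans <- matrix(c(
    0.30, 0.20, 0.25, 0.25,
    0.25, 0.30, 0.20, 0.25,
    0.25, 0.20, 0.30, 0.25,
    0.20, 0.25, 0.25, 0.30
  ), 4L, 4L, byrow = TRUE, dimnames = list(.BASES, .BASES))
  structure(
    list(trans = trans, init = stats::setNames(rep(0.25, 4L), .BASES),
         n_dinuc = NA_integer_, n_skipped = 0L, alpha = 0),
    class = "background_model"
  )
}

#' Sample first-order Markov background sequences
#'
#' @param n_seqs Number of sequences.
#' @param length Length of each sequence.
#' @param bg A `background_model` (rows of `trans` sum to 1).
#' @param seed Integer seed; the same seed reproduces the same sequences.
#' @return Character vector of sequences.
#' @export
sample_background <- function(n_seqs, length, bg = default_background(),
                              seed = 1L) {
  stopifnot(inherits(bg, "background_model"), n_seqs >= 1L, length >= 1L)
  if (any(abs(rowSums(bg$trans) - 1) > 1e-8) || any(bg$trans < 0)) {
    stop("invalid transition matrix: rows must be probability distributions",
         call. = FALSE)
  }
  codes <- with_preserved_seed({
    set.seed(seed)
    .markov_codes(as.integer(n_seqs), as.integer(length),
                  cumsum(bg$init), t(apply(bg$trans, 1L, cumsum)))
  })
  apply(codes, 1L, function(row) paste(.BASES[row], collapse = ""))
}

#' Specify a planted motif
#'
#' One or two motif subtypes, each a consensus string with `fidelity`
#' probability mass on the consensus base per column and the remainder
#' spread uniformly over the other three bases.  `ic_per_column` may be
#' given instead of `fidelity`, in which case the fidelity reproducing
#' that per-column information content is solved for numerically.
#' `pair_dependence` introduces first-order positional dependence: with
#' that probability a sampled base copies its left neighbor instead of
#' being drawn from its own column, which leaves mononucleotide columns
#' (nearly) unchanged only when they are uniform but creates informative
#' adjacent-pair structure.
#'
#' @param consensus Character vector of 1 or 2 equal-length consensus
#'   strings (2 = two motif subtypes).
#' @param fidelity Per-column probability of the consensus base, in
#'   (0.25, 1].
#' @param ic_per_column Alternative to `fidelity`: target per-column
#'   information content in bits, in (0, 2].
#' @param mix Probability of subtype 1 when two subtypes are given.
#' @param pair_dependence Probability in [0, 1) of copying the previous
#'   base.
#' @return Object of class `motif_spec`: `l`, `profiles` (list of 4 x l
#'   column-distribution matrices), `mix`, `pair_dependence`,
#'   `consensus`.
#' @export
motif_spec <- function(consensus, fidelity = NULL, ic_per_column = NULL,
                       mix = 0.5, pair_dependence = 0) {
  consensus <- toupper(consensus)
  stopifnot(length(consensus) %in% c(1L, 2L),
            pair_dependence >= 0, pair_dependence < 1,
            mix > 0, mix < 1 || length(consensus) == 1L)
  if (length(unique(nchar(consensus))) != 1L) {
    stop("consensus strings must have equal length", call. = FALSE)
  }
  if (is.null(fidelity)) {
    if (is.null(ic_per_column)) {
      stop("supply either `fidelity` or `ic_per_column`", call. = FALSE)
    }
    fidelity <- fidelity_for_ic(ic_per_column)
  }
  stopifnot(fidelity > 0.25, fidelity <= 1)
  profiles <- lapply(consensus, function(cs) {
    codes <- site_code_matrix(cs)
    l <- ncol(codes)
    M <- matrix((1 - fidelity) / 3, 4L, l, dimnames = list(.BASES, NULL))
    M[cbind(codes[1L, ], seq_len(l))] <- fidelity
    M
  })
  structure(
    list(l = nchar(consensus[1L]), profiles = profiles,
         mix = if (length(consensus) == 2L) c(mix, 1 - mix) else 1,
         pair_dependence = pair_dependence, fidelity = fidelity,
         consensus = consensus),
    class = "motif_spec"
  )
}

#' Two-subtype motif specification
#'
#' Convenience wrapper around [motif_spec()] for a motif with two
#' subtypes, each column placing `fidelity` mass on its consensus base.
#'
#' @param consensus1,consensus2 Equal-length consensus strings.
#' @inheritParams motif_spec
#' @return A `motif_spec` with two subtypes.
#' @export
make_two_subtype_spec <- function(consensus1, consensus2, fidelity = 0.9,
                                  mix = 0.5) {
  motif_spec(c(consensus1, consensus2), fidelity = fidelity, mix = mix)
}

#' Fidelity giving a target per-column information content
#'
#' Solves `IC(p) = 2 + p log2 p + (1 - p) log2((1 - p) / 3)` for the
#' consensus-base probability `p` in (0.25, 1].
#'
#' @param ic Target information content in bits, in (0, 2].
#' @return Fidelity `p`.
#' @export
fidelity_for_ic <- function(ic) {
  stopifnot(ic > 0, ic <= 2)
  if (ic == 2) return(1)
  col_ic <- function(p) {
    2 + p * log2(p) + (1 - p) * log2((1 - p) / 3)
  }
  stats::uniroot(function(p) col_ic(p) - ic,
                 lower = 0.2500001, upper = 0.9999999, tol = 1e-10)$root
}

# draw n sites from one column-profile matrix, with optional left-copy
# dependence
sample_profile_sites <- function(profile, n, pair_dependence) {
  l <- ncol(profile)
  codes <- matrix(0L, n, l)
  codes[, 1L] <- sample.int(4L, n, replace = TRUE, prob = profile[, 1L])
  for (i in seq_len(l - 1L)) {
    drawn <- sample.int(4L, n, replace = TRUE, prob = profile[, i + 1L])
    if (pair_dependence > 0) {
      copy <- stats::runif(n) < pair_dependence
      codes[, i + 1L] <- ifelse(copy, codes[, i], drawn)
    } else {
      codes[, i + 1L] <- drawn
    }
  }
  apply(codes, 1L, function(row) paste(.BASES[row], collapse = ""))
}

#' Sample aligned sites from a motif specification
#'
#' @param spec A `motif_spec`.
#' @param n Number of sites.
#' @param seed Integer seed.
#' @return List with `sites` (character) and `subtype` (integer labels).
#' @export
sample_sites <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "motif_spec"), n >= 1L)
  with_preserved_seed({
    set.seed(seed)
    subtype <- if (length(spec$profiles) == 2L) {
      ifelse(stats::runif(n) < spec$mix[1L], 1L, 2L)
    } else {
      rep(1L, n)
    }
    sites <- character(n)
    for (m in seq_along(spec$profiles)) {
      idx <- which(subtype == m)
      if (length(idx) > 0L) {
        sites[idx] <- sample_profile_sites(spec$profiles[[m]], length(idx),
                                           spec$pair_dependence)
      }
    }
    list(sites = sites, subtype = subtype)
  })
}

#' Plant motif sites in background sequences
#'
#' Each generated sequence is background flank + site + background flank,
#' with the site drawn from the motif specification (subtype chosen by the
#' mixing proportion) on the forward strand.  The recorded 0-based
#' half-open coordinates always recover the planted site exactly.
#'
#' @param spec A `motif_spec`.
#' @param n_sites Number of sequences/sites.
#' @param flank_length Background flank length on each side.
#' @param bg A `background_model`.
#' @param seed Integer seed.
#' @return Object of class `synthetic_dataset`: `seqs` (named character),
#'   `sites` (character), `coords` (data.frame `seq_id`, `start`, `end`,
#'   `strand`), `subtype`, `spec`, `bg`, `flank_length`, `seed`.
#' @export
plant_motif <- function(spec, n_sites, flank_length = 50L,
                        bg = default_background(), seed = 1L) {
  stopifnot(inherits(spec, "motif_spec"), n_sites >= 1L, flank_length >= 0L)
  drawn <- sample_sites(spec, n_sites, seed = derive_seed(seed, 101L))
  l <- spec$l
  if (flank_length > 0L) {
    left <- sample_background(n_sites, flank_length, bg,
                              seed = derive_seed(seed, 102L))
    right <- sample_background(n_sites, flank_length, bg,
                               seed = derive_seed(seed, 103L))
  } else {
    left <- right <- rep("", n_sites)
  }
  seqs <- paste0(left, drawn$sites, right)
  names(seqs) <- sprintf("seq%04d", seq_len(n_sites))
  coords <- data.frame(
    seq_id = names(seqs),
    start = rep(flank_length, n_sites),
    end = rep(flank_length + l, n_sites),
    strand = "+",
    stringsAsFactors = FALSE
  )
  structure(
    list(seqs = seqs, sites = drawn$sites, coords = coords,
         subtype = drawn$subtype, spec = spec, bg = bg,
         flank_length = as.integer(flank_length), seed = as.integer(seed)),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d sequences, site length %d, flanks %d, %d subtype(s), seed %d\n",
    length(x$seqs), x$spec$l, x$flank_length, length(x$spec$profiles),
    x$seed))
  invisible(x)
}

#' Write a synthetic dataset to FASTA + BED + manifest
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`fasta`, `bed`, `sites`,
#'   `manifest`).
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fasta = file.path(dir, "sequences.fa"),
    bed = file.path(dir, "sites.bed"),
    sites = file.path(dir, "sites.txt"),
    manifest = file.path(dir, "manifest.txt")
  )
  write_fasta(ds$seqs, paths$fasta)
  bed <- data.frame(ds$coords$seq_id, ds$coords$start, ds$coords$end,
                    paste0("site_subtype", ds$subtype),
                    0L, ds$coords$strand)
  utils::write.table(bed, paths$bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(ds$sites, paths$sites)
  writeLines(c(
    sprintf("site_length=%d", ds$spec$l),
    sprintf("n_sites=%d", length(ds$sites)),
    sprintf("flank_length=%d", ds$flank_length),
    sprintf("subtypes=%d", length(ds$spec$profiles)),
    sprintf("consensus=%s", paste(ds$spec$consensus, collapse = ",")),
    sprintf("fidelity=%.10g", ds$spec$fidelity),
    sprintf("pair_dependence=%.10g", ds$spec$pair_dependence),
    sprintf("seed=%d", ds$seed)
  ), paths$manifest)
  invisible(paths)
}
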