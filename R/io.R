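# Readers and writers for the plain-text formats the tool touches.

#' Read aligned binding sites
#'
#' Supports a plain one-uppercase-site-per-line dialect and FASTA of
#' aligned sites.  Input is uppercased, `U` is mapped to `T`, blank lines
#' are skipped; any character outside ACGT or ragged site lengths raise an
#' error naming the offending entries.
#'
#' @param path File path.
#' @param dialect `"auto"` (FASTA if the first non-blank line starts with
#'   `>`), `"plain"` or `"fasta"`.
#' @return A [site_set()].
#' @export
read_sites <- function(path, dialect = c("auto", "plain", "fasta")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) stop(sprintf("empty sites file: %s", path),
                                   call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (startsWith(nonblank[1L], ">")) "fasta" else "plain"
  }
  if (dialect == "fasta") {
    seqs <- Biostrings::readBStringSet(path)
    raw <- as.character(seqs)
    labels <- sub("\\s.*$", "", names(seqs))
    raw <- unname(raw)
  } else {
    keep <- nzchar(trimws(lines))
    raw <- trimws(lines[keep])
    labels <- paste0("line ", which(keep))
  }
  sites <- chartr("U", "T", toupper(raw))
  bad <- grepl("[^ACGT]", sites)
  if (any(bad)) {
    stop(sprintf("non-ACGT characters in %s (%s)", path,
                 paste(utils::head(labels[bad], 5L), collapse = ", ")),
         call. = FALSE)
  }
  lens <- nchar(sites)
  if (length(unique(lens)) != 1L) {
    off <- labels[lens != stats::median(lens)]
    stop(sprintf("ragged site lengths in %s (e.g. %s)", path,
                 paste(utils::head(off, 5L), collapse = ", ")),
         call. = FALSE)
  }
  site_set(sites)
}

#' Write aligned sites, one per line
#'
#' @param sites Character vector or [site_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  writeLines(as_site_chr(sites), path)
  invisible(path)
}

#' Read a multi-record FASTA file
#'
#' @param path File path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read BED3+ intervals
#'
#' 0-based half-open intervals; at least three tab-separated columns.
#' Malformed lines are reported with their line numbers.
#'
#' @param path File path.
#' @return `data.frame` with columns `chrom`, `start`, `end`, and `name`,
#'   `score`, `strand` when present.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(lines) & !startsWith(lines, "#") &
                  !startsWith(lines, "track") & !startsWith(lines, "browser"))
  if (length(keep) == 0L) stop(sprintf("no intervals in %s", path),
                               call. = FALSE)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L)) {
    stop(sprintf("BED lines with fewer than 3 columns in %s (line %s)",
                 path, paste(utils::head(keep[ncols < 3L], 5L),
                             collapse = ", ")), call. = FALSE)
  }
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3L)))
  bad <- is.na(start) | is.na(end) | start < 0L | start >= end
  if (any(bad)) {
    stop(sprintf("malformed BED intervals in %s (line %s)", path,
                 paste(utils::head(keep[bad], 5L), collapse = ", ")),
         call. = FALSE)
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (all(ncols >= 4L)) out$name <- vapply(fields, `[`, character(1), 4L)
  if (all(ncols >= 5L)) {
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[`,
                                                    character(1), 5L)))
  }
  if (all(ncols >= 6L)) out$strand <- vapply(fields, `[`, character(1), 6L)
  out
}

#' Write hits as BED6
#'
#' @param hits `data.frame` with columns `seq_id`, `start`, `end`,
#'   `strand`, `score` and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  stopifnot(all(c("seq_id", "start", "end", "strand", "score") %in%
                  names(hits)))
  nm <- if ("name" %in% names(hits)) hits$name else
    paste0("hit", seq_len(nrow(hits)))
  bed <- data.frame(hits$seq_id, hits$start, hits$end, nm,
                    format(hits$score, trim = TRUE, digits = 10),
                    hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize a fitted query/scorer to JSON
#'
#' Stores the method tag, site length, subspace, weight scheme, the query
#' vector(s), the ODV intercept and any IC weights used, so a scan can be
#' reproduced without refitting.
#'
#' @param scorer A fitted scorer.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_query <- function(scorer, path) {
  cfg <- scorer$cfg
  payload <- switch(class(scorer)[1L],
    npv_query = list(method = "npv", vector = unname(scorer$t)),
    odv_query = list(method = "odv", vector = unname(scorer$beta),
                     intercept = scorer$b, C = scorer$C),
    knpv_query = list(method = "knpv",
                      vectors = lapply(seq_len(scorer$k), function(m) {
                        unname(scorer$ts[, m])
                      }),
                      labels = scorer$labels),
    kodv_query = list(method = "kodv",
                      vectors = lapply(seq_len(scorer$k), function(m) {
                        unname(scorer$dirs[, m])
                      }),
                      labels = scorer$labels, C = scorer$C),
    pssm_scorer = list(method = "pssm",
                       log_mono = unname(scorer$log_mono)),
    ulpb_scorer = list(method = "ulpb", log_f1 = unname(scorer$log_f1),
                       log_ratio = unname(scorer$log_ratio)),
    stop("unsupported scorer class", call. = FALSE)
  )
  if (!is.null(cfg)) {
    payload$l <- cfg$l
    payload$subspace <- cfg$subspace
    payload$weights <- cfg$weights
    if (!is.null(cfg$ic)) {
      payload$ic <- list(mono = unname(cfg$ic$mono),
                         adj = unname(cfg$ic$adj),
                         gap = unname(cfg$ic$gap))
    }
  } else {
    payload$l <- scorer$l
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Deserialize a query/scorer written by [write_query()]
#'
#' @param path JSON file path.
#' @return A fitted scorer object.
#' @export
read_query <- function(path) {
  q <- jsonlite::read_json(path, simplifyVector = TRUE)
  l <- as.integer(q$l)
  cfg <- NULL
  if (!is.null(q$subspace)) {
    ic <- NULL
    if (!is.null(q$ic)) {
      ic <- structure(list(mono = q$ic$mono, adj = q$ic$adj,
                           gap = q$ic$gap), class = "ic_profile")
    }
    cfg <- embedding_config(l, q$weights, q$subspace, ic = ic)
  }
  switch(q$method,
    npv = structure(list(t = q$vector, cfg = cfg),
                    class = c("npv_query", "tfbs_scorer")),
    odv = structure(list(beta = q$vector, b = q$intercept, C = q$C,
                         cfg = cfg),
                    class = c("odv_query", "tfbs_scorer")),
    knpv = structure(list(ts = as_query_columns(q$vectors),
                          labels = q$labels,
                          k = ncol(as_query_columns(q$vectors)),
                          cfg = cfg),
                     class = c("knpv_query", "tfbs_scorer")),
    kodv = structure(list(dirs = as_query_columns(q$vectors),
                          labels = q$labels,
                          k = ncol(as_query_columns(q$vectors)),
                          C = q$C, cfg = cfg),
                     class = c("kodv_query", "tfbs_scorer")),
    pssm = structure(list(log_mono = matrix(unlist(q$log_mono), 4L, l,
                                            dimnames = list(.BASES, NULL)),
                          l = l),
                     class = c("pssm_scorer", "tfbs_scorer")),
    ulpb = structure(list(log_f1 = unlist(q$log_f1),
                          log_ratio = array(unlist(q$log_ratio),
                                            dim = c(4L, 4L, l - 1L)),
                          l = l),
                     class = c("ulpb_scorer", "tfbs_scorer")),
    stop(sprintf("unknown method '%s' in %s", q$method, path),
         call. = FALSE)
  )
}

# one column per stored sub-query vector, whether jsonlite simplified the
# serialized list to a matrix or kept it as a list
as_query_columns <- function(vectors) {
  if (is.matrix(vectors)) t(vectors) else
    do.call(cbind, lapply(vectors, as.numeric))
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Unknown keys
#' (not in `allowed`) are rejected.
#'
#' @param path File path.
#' @param allowed Optional character vector of permitted keys.
#' @return Named character vector.
#' @export
read_config <- function(path, allowed = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  m <- regmatches(lines, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$", lines))
  bad <- lengths(m) != 3L
  if (any(bad)) {
    stop(sprintf("malformed config line(s) in %s: %s", path,
                 paste(utils::head(lines[bad], 3L), collapse = "; ")),
         call. = FALSE)
  }
  keys <- vapply(m, `[`, character(1), 2L)
  vals <- trimws(vapply(m, `[`, character(1), 3L))
  if (!is.null(allowed)) {
    unknown <- setdiff(keys, allowed)
    if (length(unknown) > 0L) {
      stop(sprintf("unknown config key(s) in %s: %s", path,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  stats::setNames(vals, keys)
}
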