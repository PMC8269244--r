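#' Alignment backend: tabular-hit parsing, built-in aligners, hit filtering
#'
#' The classifier consumes local-alignment hits in the 12/13-column BLAST
#' `outfmt 6` dialect from any backend. Two built-in backends are provided:
#' an exact Smith-Waterman aligner ([local_align()]) for small instances and
#' oracle checks, and a k-mer seeded ungapped aligner ([align_reads()]) fast
#' enough for whole simulated read sets.
#'
#' @name align
NULL

.HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore")

# Karlin-Altschul style monotone transform of the raw score; calibrated for
# thresholding only (ungapped DNA lambda/K), not for database-search p-values.
.synth_bitscore <- function(score, lambda = 1.33, K = 0.621) {
  (lambda * score - log(K)) / log(2)
}

.synth_evalue <- function(bitscore, query_len, search_space) {
  as.numeric(query_len) * as.numeric(search_space) * 2^(-bitscore)
}

#' Parse tabular alignment hits (BLAST outfmt-6 dialect)
#'
#' Accepts the canonical 12 columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore) plus an optional 13th
#' `qcovs` column. When `qcovs` is absent, query coverage is derived as
#' `100 * length / query_length`, which requires `query_lengths`.
#'
#' @param path file path (or connection) to the TSV; no header line
#' @param query_lengths named numeric vector of query lengths, required to
#'   derive coverage when the file has no `qcovs` column
#' @return data.frame of hits with a `qcovs` column
#' @export
parse_tabular_hits <- function(path, query_lengths = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), 13L),
                                  c(.HIT_COLS, "qcovs")))
    for (cl in c(.HIT_COLS[-(1:2)], "qcovs")) out[[cl]] <- numeric(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  bad <- which(!(ncol %in% c(12L, 13L)))
  if (length(bad))
    stop("malformed hit rows (expected 12 or 13 tab-separated columns) at line(s): ",
         paste(head(bad, 10L), collapse = ", "))
  has_qcovs <- ncol[1L] == 13L
  if (any(ncol != ncol[1L]))
    stop("inconsistent column counts at line(s): ",
         paste(head(which(ncol != ncol[1L]), 10L), collapse = ", "))
  mat <- do.call(rbind, parts)
  out <- data.frame(qseqid = mat[, 1L], sseqid = mat[, 2L],
                    stringsAsFactors = FALSE)
  num_cols <- c(.HIT_COLS[-(1:2)], if (has_qcovs) "qcovs")
  for (j in seq_along(num_cols)) {
    v <- suppressWarnings(as.numeric(mat[, j + 2L]))
    if (anyNA(v))
      stop("non-numeric value in column '", num_cols[j], "' at line(s): ",
           paste(head(which(is.na(v)), 10L), collapse = ", "))
    out[[num_cols[j]]] <- v
  }
  if (!has_qcovs) {
    if (is.null(query_lengths))
      stop("file has no qcovs column; supply query_lengths to derive coverage")
    qlen <- query_lengths[out$qseqid]
    if (anyNA(qlen))
      stop("query_lengths missing for: ",
           paste(unique(out$qseqid[is.na(qlen)]), collapse = ", "))
    out$qcovs <- 100 * out$length / as.numeric(qlen)
  }
  out
}

#' Exact local alignment (Smith-Waterman) of two sequences
#'
#' Optimal local alignment under linear gap scoring, searching both strands
#' (the reverse strand via the query's reverse complement). Intended for
#' small instances (subjects up to ~100 kb); whole read sets should use
#' [align_reads()].
#'
#' @param query,subject DNA strings over A/C/G/T/N
#' @param match,mismatch,gap scoring parameters (defaults +1/-1/-2)
#' @param query_id,subject_id identifiers copied into the hit record
#' @return one-row data.frame in the standard hit layout (plus `qcovs` and
#'   `strand`), or `NULL` when no positive-scoring alignment exists
#' @export
local_align <- function(query, subject, match = 1, mismatch = -1, gap = -2,
                        query_id = "query", subject_id = "subject") {
  if (!nzchar(query) || !nzchar(subject))
    stop("local_align: empty sequence")
  r <- .sw_align_cpp(as.character(query), as.character(subject),
                     match, mismatch, gap, TRUE)
  if (!isTRUE(r$found)) return(NULL)
  qlen <- nchar(query)
  bit <- .synth_bitscore(r$score)
  data.frame(
    qseqid = query_id, sseqid = subject_id,
    pident = 100 * r$matches / r$align_length,
    length = r$align_length,
    mismatch = r$align_length - r$matches, gapopen = 0L,
    qstart = r$q_start, qend = r$q_end,
    sstart = r$s_start, send = r$s_end,
    evalue = .synth_evalue(bit, qlen, nchar(subject)),
    bitscore = bit,
    qcovs = 100 * (r$q_end - r$q_start + 1) / qlen,
    strand = r$strand,
    stringsAsFactors = FALSE)
}

#' Align a read set against reference sequences with the seeded aligner
#'
#' Builds a k-mer index over the subject sequences and reports, per query and
#' subject, the best ungapped alignment found on either strand. Suited to
#' substitution-dominated short reads and to exact long queries (contigs);
#' indel-rich long reads need an external gapped backend emitting the same
#' tabular format.
#'
#' @param queries named character vector (or `DNAStringSet`) of query reads
#' @param subjects named character vector (or `DNAStringSet`) of reference
#'   sequences; names become `sseqid`
#' @param k seed length in bases (default 15)
#' @param max_targets maximum subjects reported per query (default 50)
#' @return data.frame of hits in the standard layout with `qcovs` and `strand`
#' @export
align_reads <- function(queries, subjects, k = 15, max_targets = 50) {
  qs <- as.character(queries)
  ss <- as.character(subjects)
  qn <- names(queries)
  sn <- names(subjects)
  if (is.null(qn) || is.null(sn))
    stop("queries and subjects must be named")
  hits <- .seed_align_cpp(qs, ss, k = as.integer(k),
                          max_targets = as.integer(max_targets))
  if (nrow(hits) == 0L) {
    return(data.frame(qseqid = character(0), sseqid = character(0),
                      pident = numeric(0), length = numeric(0),
                      mismatch = numeric(0), gapopen = numeric(0),
                      qstart = numeric(0), qend = numeric(0),
                      sstart = numeric(0), send = numeric(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      qcovs = numeric(0), strand = character(0)))
  }
  qlen <- nchar(qs)[hits$query_idx]
  bit <- .synth_bitscore(hits$score)
  data.frame(
    qseqid = qn[hits$query_idx], sseqid = sn[hits$subject_idx],
    pident = hits$pident, length = hits$length,
    mismatch = hits$mismatch, gapopen = 0L,
    qstart = hits$qstart, qend = hits$qend,
    sstart = hits$sstart, send = hits$send,
    evalue = .synth_evalue(bit, qlen, sum(as.numeric(nchar(ss)))),
    bitscore = bit,
    qcovs = 100 * (hits$qend - hits$qstart + 1) / qlen,
    strand = hits$strand,
    stringsAsFactors = FALSE)
}

#' Filter and rank alignment hits
#'
#' Applies the E-value and query-coverage gates and keeps at most `max_hits`
#' hits per query, ordered by bit score (ties broken by higher identity, then
#' subject identifier). Defaults follow the profiling pipeline's balanced
#' settings: E <= 1e-5, coverage >= 95%, 100 hits.
#'
#' @param hits data.frame of hits (standard layout with `qcovs`)
#' @param evalue_max maximum E-value (default 1e-5)
#' @param min_query_cov minimum query coverage percent (default 95)
#' @param max_hits maximum retained hits per query (default 100)
#' @return filtered, sorted data.frame (subset of the input rows)
#' @export
filter_hits <- function(hits, evalue_max = 1e-5, min_query_cov = 95,
                        max_hits = 100) {
  keep <- hits$evalue <= evalue_max & hits$qcovs >= min_query_cov
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$qseqid, -hits$bitscore, -hits$pident, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(hits)), hits$qseqid, FUN = seq_along)
  out <- hits[idx <= max_hits, , drop = FALSE]
  rownames(out) <- NULL
  out
}
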