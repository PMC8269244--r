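#' Read-level functional profiling
#'
#' Profiles reads against labelled functional reference sequences:
#' carbohydrate-active-enzyme style family codes (GH/GT/PL/CE/CBM) with
#' metabolic-pathway rollups. Each read is credited to the family of its best
#' passing hit (bit score; ties broken by lexicographic family order); its
#' best-hit reference's pathways are all incremented, so pathway counts are
#' deliberately non-exclusive. Functional gates are configured separately
#' from the taxonomic ones; coverage defaults to 50% because reads may span
#' domain boundaries.
#'
#' @name funcprofiler
NULL

#' Read a labelled functional reference FASTA
#'
#' Header dialect: `>seq_id|family|pw1,pw2` (the pathway list may be empty:
#' `>seq_id|family|`).
#'
#' @param path FASTA file
#' @return data.frame with `seq_id`, `sequence`, `family`, `pathways`
#'   (list column)
#' @export
read_labeled_fasta <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop("labelled FASTA headers must be 'seq_id|family|pathways'; bad: ",
         paste(head(names(seqs)[bad], 5L), collapse = ", "))
  fam <- vapply(parts, `[`, "", 2L)
  if (any(!nzchar(fam))) stop("empty family label(s) in labelled FASTA")
  pw <- lapply(parts, function(p)
    if (length(p) >= 3L && nzchar(p[3L]))
      strsplit(p[3L], ",", fixed = TRUE)[[1]] else character(0))
  out <- data.frame(seq_id = vapply(parts, `[`, "", 1L),
                    sequence = unname(seqs), family = fam,
                    stringsAsFactors = FALSE)
  out$pathways <- pw
  out
}

#' Profile functional families from per-read hits
#'
#' @param hits data.frame of read-vs-functional-reference hits (standard
#'   layout; `sseqid` must match `refs$seq_id`)
#' @param refs labelled reference data.frame (see [read_labeled_fasta()])
#' @param n_reads total number of input reads (to count unassigned ones);
#'   defaults to the number of distinct queries in `hits`
#' @param evalue_max,min_query_cov functional gates (defaults 1e-5 and 50)
#' @return a `function_profile`: `family_counts`, `family_relative` (percent
#'   over assigned reads), `pathway_counts`, `assigned`, `unassigned`,
#'   `best_hits` (read -> reference)
#' @export
profile_families <- function(hits, refs, n_reads = NULL,
                             evalue_max = 1e-5, min_query_cov = 50) {
  unknown <- setdiff(unique(hits$sseqid), refs$seq_id)
  if (length(unknown))
    stop("hits cite unknown reference(s): ", paste(unknown, collapse = ", "))
  if (is.null(n_reads)) n_reads <- length(unique(hits$qseqid))
  keep <- hits$evalue <= evalue_max & hits$qcovs >= min_query_cov
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(structure(list(family_counts = integer(0),
                          family_relative = numeric(0),
                          pathway_counts = integer(0),
                          assigned = 0L, unassigned = n_reads,
                          best_hits = character(0)),
                     class = "function_profile"))
  }
  fam <- refs$family[match(h$sseqid, refs$seq_id)]
  ord <- order(h$qseqid, -h$bitscore, fam, h$sseqid)
  h <- h[ord, , drop = FALSE]
  first <- !duplicated(h$qseqid)
  best <- h[first, , drop = FALSE]
  best_fam <- refs$family[match(best$sseqid, refs$seq_id)]
  fc <- table(best_fam)
  pw <- unlist(refs$pathways[match(best$sseqid, refs$seq_id)])
  pc <- if (length(pw)) table(pw) else
    table(factor(character(0)))
  structure(list(
    family_counts = setNames(as.integer(fc), names(fc)),
    family_relative = setNames(100 * as.integer(fc) / nrow(best), names(fc)),
    pathway_counts = setNames(as.integer(pc), names(pc)),
    assigned = nrow(best), unassigned = n_reads - nrow(best),
    best_hits = setNames(best$sseqid, best$qseqid)),
    class = "function_profile")
}

#' @export
print.function_profile <- function(x, ...) {
  cat("function_profile:", x$assigned, "assigned /", x$unassigned,
      "unassigned reads;", length(x$family_counts), "families,",
      length(x$pathway_counts), "pathways\n")
  invisible(x)
}

#' Roll family assignments up to pathways
#'
#' Recomputes the pathway table from a profile's best-hit map: every pathway
#' listed on a read's best-hit reference is incremented, so the column sums
#' can exceed the number of assigned reads.
#'
#' @param profile a `function_profile`
#' @param refs labelled reference data.frame
#' @return named integer vector of pathway counts
#' @export
rollup_pathways <- function(profile, refs) {
  pw <- unlist(refs$pathways[match(profile$best_hits, refs$seq_id)])
  if (length(pw) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(pw)
  setNames(as.integer(tab), names(tab))
}

#' End-to-end functional profiling of reads
#'
#' @param reads read data.frame
#' @param refs labelled reference data.frame
#' @param ... gates passed to [profile_families()]
#' @return a `function_profile`
#' @export
profile_function <- function(reads, refs, ...) {
  hits <- align_reads(setNames(reads$sequence, reads$read_id),
                      setNames(refs$sequence, refs$seq_id))
  profile_families(hits, refs, n_reads = nrow(reads), ...)
}
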