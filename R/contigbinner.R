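#' Assembled-contig classification, binning and GenBank export
#'
#' Contigs longer than 5 kbp are classified with the same best-hit/LCA rules
#' as reads, pooled per assigned taxon, annotated with a minimal ORF caller,
#' and written as one GenBank flat file per taxon for genome-browser
#' inspection. The read classifier's query-coverage gate is not applied to
#' contigs (a long contig rarely aligns end-to-end against a draft
#' reference); instead hits must span at least `min_hit_span` bases.
#'
#' @name contigbinner
NULL

#' Classify assembled contigs
#'
#' @param contigs named character vector (or `DNAStringSet`) of contigs
#' @param db a `reference_db`
#' @param params a [classifier_params()]; `min_query_cov` is ignored for
#'   contigs
#' @param contig_min_length contigs at or below this length are skipped and
#'   reported as `too_short` (default 5000, strict `>` to classify)
#' @param min_hit_span minimum alignment span in bases for a contig hit
#'   (default 1000)
#' @param hits optional precomputed hit table (standard layout); defaults to
#'   the built-in seeded aligner
#' @param tree optional `taxonomy_tree`
#' @return data.frame: `contig_id`, `length`, `taxid`, `assigned_rank`
#'   (species/genus/higher/unclassified/too_short), `method`,
#'   `best_identity`, `species_label`
#' @export
classify_contigs <- function(contigs, db, params = classifier_params(),
                             contig_min_length = 5000, min_hit_span = 1000,
                             hits = NULL, tree = NULL) {
  seqs <- setNames(as.character(contigs), names(contigs))
  if (is.null(names(seqs))) stop("contigs must be named")
  len <- nchar(seqs)
  long <- len > contig_min_length
  if (is.null(tree)) tree <- taxonomy_from_labels(db$labels)
  ns <- sum(!long)
  out_short <- data.frame(
    contig_id = names(seqs)[!long], length = len[!long],
    taxid = rep(NA_character_, ns),
    assigned_rank = rep("too_short", ns), method = rep("none", ns),
    best_identity = rep(NA_real_, ns),
    species_label = rep(NA_character_, ns),
    stringsAsFactors = FALSE)
  if (!any(long)) return(out_short)
  if (is.null(hits))
    hits <- align_reads(seqs[long], db_sequences(db))
  hits <- hits[hits$qseqid %in% names(seqs)[long], , drop = FALSE]
  # contig gates: E-value and minimum spanned bases, no query-coverage gate
  contig_params <- params
  contig_params$min_query_cov <- 0
  hits <- hits[hits$length >= min_hit_span, , drop = FALSE]
  cls <- classify_reads(hits, tree, db$labels, contig_params,
                        read_ids = names(seqs)[long])
  out_long <- data.frame(
    contig_id = cls$read_id, length = len[match(cls$read_id, names(seqs))],
    taxid = cls$taxid, assigned_rank = cls$assigned_rank,
    method = cls$method, best_identity = cls$best_identity,
    species_label = cls$species_label, stringsAsFactors = FALSE)
  out <- rbind(out_long, out_short)
  out[match(names(seqs), out$contig_id), , drop = FALSE]
}

#' Pool contigs by assigned taxon
#'
#' @param contigs named character vector of contigs
#' @param classifications data.frame from [classify_contigs()]
#' @return named list of named character vectors: one pool per assigned
#'   taxid, plus an `unclassified` pool (unclassified and too-short contigs)
#' @export
bin_by_taxon <- function(contigs, classifications) {
  seqs <- setNames(as.character(contigs), names(contigs))
  cl <- classifications[match(names(seqs), classifications$contig_id), ]
  key <- ifelse(is.na(cl$taxid), "unclassified", cl$taxid)
  split(seqs, key)
}

#' Fraction of assembled length that was classified
#'
#' The per-assembly accuracy summary: classified contig length over total
#' contig length, in percent.
#'
#' @param classifications data.frame from [classify_contigs()]
#' @return percent scalar
#' @export
classified_length_fraction <- function(classifications) {
  cls <- classifications$assigned_rank %in% c("species", "genus", "higher")
  100 * sum(classifications$length[cls]) / sum(classifications$length)
}

.GENETIC_STOPS <- c("TAA", "TAG", "TGA")

# ORFs on the forward strand of one sequence; coordinates 1-based inclusive,
# ATG through stop codon
.orfs_forward <- function(seq, min_orf_nt) {
  n <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0L) next
    codons <- substring(seq, starts, starts + 2L)
    is_stop <- codons %in% .GENETIC_STOPS
    is_atg <- codons == "ATG"
    seg <- cumsum(c(TRUE, head(is_stop, -1L)))  # segment id after each stop
    for (s in split(seq_along(codons), seg)) {
      stops <- s[is_stop[s]]
      if (length(stops) == 0L) next
      stop_i <- stops[1L]
      atgs <- s[is_atg[s] & s < stop_i]
      if (length(atgs) == 0L) next
      start_i <- atgs[1L]
      nt <- (stop_i - start_i + 1L) * 3L
      if (nt < min_orf_nt) next
      out[[length(out) + 1L]] <- c(start = starts[start_i],
                                   end = starts[stop_i] + 2L,
                                   frame = frame + 1L)
    }
  }
  out
}

#' Call open reading frames on six frames
#'
#' Maximal ATG-to-stop ORFs (stop codon included in the coordinates) of at
#' least `min_orf_nt` bases, on both strands. A deliberate minimal stand-in
#' for a full gene predictor: the GenBank structure, not annotation quality,
#' is the contract.
#'
#' @param sequence DNA string over A/C/G/T/N
#' @param min_orf_nt minimum ORF length in bases, ATG through stop
#'   (default 300)
#' @param contig_id identifier copied into the features
#' @return data.frame: `contig_id`, `start`, `end` (1-based inclusive, on the
#'   forward strand), `strand`, `frame`, `product`
#' @export
call_orfs <- function(sequence, min_orf_nt = 300, contig_id = "contig") {
  sequence <- toupper(as.character(sequence))
  n <- nchar(sequence)
  fwd <- .orfs_forward(sequence, min_orf_nt)
  rev <- .orfs_forward(.revcomp(sequence), min_orf_nt)
  rows <- list()
  for (o in fwd)
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = contig_id, start = o[["start"]], end = o[["end"]],
      strand = "+", frame = o[["frame"]], product = "hypothetical protein",
      stringsAsFactors = FALSE)
  for (o in rev)
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = contig_id, start = n - o[["end"]] + 1L,
      end = n - o[["start"]] + 1L, strand = "-", frame = o[["frame"]],
      product = "hypothetical protein", stringsAsFactors = FALSE)
  if (length(rows) == 0L)
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame = integer(0), product = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

.gb_wrap_location <- function(start, end, strand) {
  loc <- paste0(start, "..", end)
  if (strand == "-") paste0("complement(", loc, ")") else loc
}

#' Write a contig pool as a GenBank flat file
#'
#' One LOCUS per contig with source and CDS features (coordinates and
#' `/product` qualifiers) and the pool's taxon lineage as ORGANISM; the
#' output parses with standard GenBank readers.
#'
#' @param pool named character vector of contigs sharing a taxon
#' @param features data.frame of [call_orfs()] features for these contigs
#' @param path output file
#' @param organism organism name for the pool (default "unclassified")
#' @param lineage character vector of lineage names, root excluded
#' @return invisible `path` (`NULL` without writing when the pool is empty)
#' @export
write_genbank <- function(pool, features, path, organism = "unclassified",
                          lineage = character(0)) {
  if (length(pool) == 0L) {
    message("empty contig pool; no GenBank file written")
    return(invisible(NULL))
  }
  bad <- features$end > nchar(pool[features$contig_id]) | features$start < 1
  if (any(bad))
    stop("feature outside contig bounds: ",
         paste(head(features$contig_id[bad], 5L), collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  for (cid in names(pool)) {
    seq <- tolower(pool[[cid]])
    n <- nchar(seq)
    locus_name <- gsub("[^A-Za-z0-9_.-]", "_", cid)
    writeLines(sprintf(
      "LOCUS       %-16s%12d bp    DNA     linear   ENV %s",
      locus_name, n, toupper(format(Sys.Date(), "%d-%b-%Y"))), con)
    writeLines(sprintf("DEFINITION  %s, taxon %s.", cid, organism), con)
    writeLines(sprintf("ACCESSION   %s", locus_name), con)
    writeLines(sprintf("SOURCE      %s", organism), con)
    writeLines(sprintf("  ORGANISM  %s", organism), con)
    writeLines(sprintf("            %s.",
                       if (length(lineage)) paste(lineage, collapse = "; ")
                       else "Unclassified"), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", n), con)
    writeLines(sprintf("                     /organism=\"%s\"", organism),
               con)
    f <- features[features$contig_id == cid, , drop = FALSE]
    if (nrow(f)) {
      for (j in seq_len(nrow(f))) {
        writeLines(sprintf("     CDS             %s",
                           .gb_wrap_location(f$start[j], f$end[j],
                                             f$strand[j])), con)
        writeLines(sprintf("                     /product=\"%s\"",
                           f$product[j]), con)
      }
    }
    writeLines("ORIGIN", con)
    pos <- seq(1L, n, by = 60L)
    for (p in pos) {
      chunk <- substring(seq, p, min(p + 59L, n))
      groups <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, by = 10L),
                               nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(groups, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Classify, bin, annotate and export contigs per species
#'
#' @param contigs named character vector of contigs
#' @param db a `reference_db`
#' @param dir output directory for GenBank files
#' @param params a [classifier_params()]
#' @param ... passed to [classify_contigs()]
#' @return list: `classifications`, `pools`, `files` (written GenBank paths)
#' @export
bin_and_annotate <- function(contigs, db, dir, params = classifier_params(),
                             ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- taxonomy_from_labels(db$labels)
  cls <- classify_contigs(contigs, db, params, tree = tree, ...)
  pools <- bin_by_taxon(contigs, cls)
  files <- character(0)
  for (taxon in names(pools)) {
    pool <- pools[[taxon]]
    feats <- do.call(rbind, lapply(names(pool), function(cid)
      call_orfs(pool[[cid]], contig_id = cid)))
    org <- if (taxon == "unclassified") "unclassified" else
      taxon_name(tree, taxon)
    lin <- if (taxon == "unclassified") character(0) else
      lineage(tree, taxon)$name[-1L]
    f <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", taxon), ".gbk"))
    write_genbank(pool, feats, f, organism = org, lineage = lin)
    files <- c(files, f)
  }
  list(classifications = cls, pools = pools, files = files)
}
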