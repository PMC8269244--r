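#' Read-based taxonomic profiling
#'
#' Quality filtering, host depletion, seeded subsampling, per-read taxonomic
#' classification and profile aggregation with genome-size normalization.
#' Classification follows homology-based best-hit logic: reads whose best hit
#' exceeds the species identity cutoff (default >94%) are assigned at species
#' level; equal best hits to multiple species are resolved by least common
#' ancestor (LCA), except against viral references where LCA is disabled and
#' the highest-scoring hit wins; reads between the genus (default 20%) and
#' species cutoffs are assigned to the best hit's genus as "undefined
#' species"; reads below the genus cutoff stay unclassified.
#'
#' @name readprofiler
NULL

#' Classifier parameters
#'
#' @param species_min_identity percent identity above which (strictly) a read
#'   is classified at species level (default 94)
#' @param genus_min_identity minimum percent identity for genus-level
#'   "undefined species" classification (default 20)
#' @param evalue_max,min_query_cov,max_hits hit-filtering gates passed to
#'   [filter_hits()] (defaults 1e-5, 95, 100)
#' @param sample_size default number of reads profiled per sample
#'   (default 100000)
#' @param viral_lca_disabled disable LCA for ties among viral references and
#'   take the highest-bit-score hit instead (default TRUE); public viral
#'   genomes share so much sequence that LCA would collapse most viral reads
#' @param identity_tie_epsilon identity tolerance (percentage points) within
#'   which hits count as "equal best" (default 0)
#' @return a `classifier_params` list
#' @export
classifier_params <- function(species_min_identity = 94,
                              genus_min_identity = 20,
                              evalue_max = 1e-5,
                              min_query_cov = 95,
                              max_hits = 100,
                              sample_size = 100000,
                              viral_lca_disabled = TRUE,
                              identity_tie_epsilon = 0) {
  if (genus_min_identity > species_min_identity)
    stop("genus_min_identity must be <= species_min_identity")
  structure(list(species_min_identity = species_min_identity,
                 genus_min_identity = genus_min_identity,
                 evalue_max = evalue_max, min_query_cov = min_query_cov,
                 max_hits = max_hits, sample_size = sample_size,
                 viral_lca_disabled = viral_lca_disabled,
                 identity_tie_epsilon = identity_tie_epsilon),
            class = "classifier_params")
}

#' Quality-filter reads (mean Phred and minimum length)
#'
#' Retains reads with mean Phred quality >= `min_mean_q` and length >=
#' `min_length` (so 149-bp reads fall below the default 150 floor). In paired
#' mode (a `mate` column with values > 0) both mates are dropped when either
#' fails.
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality` (Phred+33),
#'   optionally `mate`/`pair_id`
#' @param min_mean_q minimum mean Phred score (default 25)
#' @param min_length minimum read length in bases (default 150)
#' @return list with `reads` (retained rows) and `stats` (input, retained,
#'   removed_quality, removed_length)
#' @export
quality_filter <- function(reads, min_mean_q = 25, min_length = 150) {
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    stop("sequence/quality length mismatch for read(s): ",
         paste(head(reads$read_id[nchar(reads$sequence) !=
                                  nchar(reads$quality)], 5L), collapse = ", "))
  len <- nchar(reads$sequence)
  mq <- vapply(reads$quality, function(q) mean(utf8ToInt(q)) - 33,
               numeric(1), USE.NAMES = FALSE)
  ok <- mq >= min_mean_q & len >= min_length
  paired <- !is.null(reads$mate) && any(reads$mate > 0)
  if (paired) {
    bad_pairs <- unique(reads$pair_id[!ok])
    ok <- ok & !(reads$pair_id %in% bad_pairs)
  }
  list(reads = reads[ok, , drop = FALSE],
       stats = list(input = nrow(reads), retained = sum(ok),
                    removed_quality = sum(mq < min_mean_q),
                    removed_length = sum(len < min_length)))
}

#' Remove reads matching configured host genomes
#'
#' A read is removed iff it has a host hit passing the classifier's E-value
#' and coverage gates with identity at or above the species cutoff.
#'
#' @param reads read data.frame
#' @param host_hits data.frame of read-vs-host hits (standard layout); may be
#'   `NULL` or empty when no host is configured
#' @param params a [classifier_params()]
#' @return retained reads data.frame
#' @export
deplete_host <- function(reads, host_hits, params = classifier_params()) {
  if (is.null(host_hits) || nrow(host_hits) == 0L) return(reads)
  hostish <- unique(host_hits$qseqid[
    host_hits$evalue <= params$evalue_max &
    host_hits$qcovs >= params$min_query_cov &
    host_hits$pident >= params$species_min_identity])
  reads[!(reads$read_id %in% hostish), , drop = FALSE]
}

#' Subsample reads uniformly without replacement
#'
#' Shallow profiling runs on a fixed number of reads (default 100000); the
#' sample is drawn uniformly, reproducibly for a fixed seed, and read pairs
#' are kept together (for paired input, `floor(n / 2)` pairs are drawn).
#'
#' @param reads read data.frame (optionally with `mate`/`pair_id`)
#' @param n target number of reads (default 100000)
#' @param seed integer seed
#' @return sampled reads data.frame (all reads when `n >=` available)
#' @export
subsample_reads <- function(reads, n = 100000, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (n >= nrow(reads)) return(reads)
  set.seed(seed)
  paired <- !is.null(reads$mate) && any(reads$mate > 0)
  if (paired) {
    pairs <- unique(reads$pair_id)
    take <- sample(pairs, min(floor(n / 2), length(pairs)))
    reads[reads$pair_id %in% take, , drop = FALSE]
  } else {
    reads[sort(sample.int(nrow(reads), n)), , drop = FALSE]
  }
}

# core decision rule for the (already filtered) hits of one read
.classify_one <- function(pident, bitscore, sseqid, genus, species, kingdom,
                          tree, params) {
  best <- max(pident)
  tie <- pident >= best - params$identity_tie_epsilon
  if (best > params$species_min_identity) {
    sp <- unique(species[tie])
    if (length(sp) == 1L) {
      return(list(taxid = paste0("s__", sp), assigned_rank = "species",
                  method = "best_hit", best_identity = best,
                  species_label = sp))
    }
    if (params$viral_lca_disabled && all(kingdom[tie] == "viral")) {
      ord <- order(-bitscore[tie], sseqid[tie])
      pick <- which(tie)[ord[1L]]
      return(list(taxid = paste0("s__", species[pick]),
                  assigned_rank = "species", method = "viral_best_hit",
                  best_identity = best, species_label = species[pick]))
    }
    anc <- lca(tree, paste0("s__", sp))
    r <- taxon_rank(tree, anc)
    return(list(taxid = anc,
                assigned_rank = if (r %in% c("species", "genus")) r
                                else "higher",
                method = "lca", best_identity = best,
                species_label = if (r == "species") taxon_name(tree, anc)
                                else "undefined species"))
  }
  if (best >= params$genus_min_identity) {
    ord <- order(-pident, -bitscore, sseqid)
    pick <- ord[1L]
    return(list(taxid = paste0("g__", genus[pick]), assigned_rank = "genus",
                method = "best_hit", best_identity = best,
                species_label = "undefined species"))
  }
  list(taxid = NA_character_, assigned_rank = "unclassified",
       method = "none", best_identity = best,
       species_label = NA_character_)
}

#' Classify one read from its filtered alignment hits
#'
#' @param hits data.frame of hits for a single read, already passed through
#'   [filter_hits()]
#' @param tree a `taxonomy_tree` covering the database labels (see
#'   [taxonomy_from_labels()])
#' @param labels data.frame mapping `accession` to `genus`, `species`,
#'   `kingdom` (as in a `reference_db`)
#' @param params a [classifier_params()]
#' @return one-row data.frame: `read_id`, `taxid`, `assigned_rank`
#'   (species/genus/higher/unclassified), `method` (best_hit/lca/
#'   viral_best_hit/none), `best_identity`, `species_label`
#' @export
classify_read <- function(hits, tree, labels, params = classifier_params()) {
  rid <- unique(hits$qseqid)
  if (length(rid) > 1L) stop("classify_read expects hits of a single read")
  if (nrow(hits) == 0L)
    return(data.frame(read_id = if (length(rid)) rid else NA_character_,
                      taxid = NA_character_, assigned_rank = "unclassified",
                      method = "none", best_identity = NA_real_,
                      species_label = NA_character_,
                      stringsAsFactors = FALSE))
  acc <- sub("\\|.*$", "", hits$sseqid)
  li <- match(acc, labels$accession)
  if (anyNA(li))
    stop("hit cites accession(s) absent from labels: ",
         paste(unique(acc[is.na(li)]), collapse = ", "))
  r <- .classify_one(hits$pident, hits$bitscore, hits$sseqid,
                     labels$genus[li], labels$species[li],
                     labels$kingdom[li], tree, params)
  data.frame(read_id = rid, taxid = r$taxid, assigned_rank = r$assigned_rank,
             method = r$method, best_identity = r$best_identity,
             species_label = r$species_label, stringsAsFactors = FALSE)
}

#' Classify a whole read set from a table of alignment hits
#'
#' Applies [filter_hits()] with the classifier's gates, then the per-read
#' decision rule. Reads listed in `read_ids` but absent from the hits are
#' reported unclassified.
#'
#' @param hits data.frame of hits for many reads (standard layout)
#' @param tree a `taxonomy_tree`
#' @param labels accession label table (see [classify_read()])
#' @param params a [classifier_params()]
#' @param read_ids optional character vector of all read identifiers
#' @return data.frame with one row per read
#' @export
classify_reads <- function(hits, tree, labels, params = classifier_params(),
                           read_ids = NULL) {
  hits <- filter_hits(hits, params$evalue_max, params$min_query_cov,
                      params$max_hits)
  acc <- sub("\\|.*$", "", hits$sseqid)
  li <- match(acc, labels$accession)
  if (anyNA(li))
    stop("hit cites accession(s) absent from labels: ",
         paste(unique(acc[is.na(li)]), collapse = ", "))
  dt <- data.table::data.table(
    qseqid = hits$qseqid, pident = hits$pident, bitscore = hits$bitscore,
    sseqid = hits$sseqid, genus = labels$genus[li],
    species = labels$species[li], kingdom = labels$kingdom[li])
  res <- dt[, {
    r <- .classify_one(pident, bitscore, sseqid, genus, species, kingdom,
                       tree, params)
    list(taxid = r$taxid, assigned_rank = r$assigned_rank, method = r$method,
         best_identity = r$best_identity, species_label = r$species_label)
  }, by = "qseqid"]
  out <- data.frame(read_id = res$qseqid, taxid = res$taxid,
                    assigned_rank = res$assigned_rank, method = res$method,
                    best_identity = res$best_identity,
                    species_label = res$species_label,
                    stringsAsFactors = FALSE)
  if (!is.null(read_ids)) {
    missing <- setdiff(read_ids, out$read_id)
    if (length(missing)) {
      out <- rbind(out, data.frame(
        read_id = missing, taxid = NA_character_,
        assigned_rank = "unclassified", method = "none",
        best_identity = NA_real_, species_label = NA_character_,
        stringsAsFactors = FALSE))
    }
    out <- out[match(read_ids, out$read_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Aggregate per-read classifications into a taxonomic profile
#'
#' Species-level counts keep per-genus "undefined species" bins and
#' higher-rank LCA assignments as their own rows; relative abundance is
#' `100 * count / total classified reads`. Rank tables roll counts up the
#' tree (genus and superkingdom); reads assigned above a rank are reported in
#' an `(above genus)` style bucket for that table.
#'
#' @param classifications data.frame from [classify_reads()]
#' @param tree the `taxonomy_tree` used for classification
#' @return a `taxon_profile`: `table` (taxid, label, rank, count, relative),
#'   `rank_tables`, `unclassified_count`, `total_classified`
#' @export
aggregate_profile <- function(classifications, tree) {
  cl <- classifications[classifications$assigned_rank != "unclassified", ,
                        drop = FALSE]
  uncl <- nrow(classifications) - nrow(cl)
  if (nrow(cl) == 0L) {
    tab <- data.frame(taxid = character(0), label = character(0),
                      rank = character(0), count = integer(0),
                      relative = numeric(0))
    return(structure(list(table = tab, rank_tables = list(),
                          unclassified_count = uncl, total_classified = 0L),
                     class = "taxon_profile"))
  }
  cnt <- table(cl$taxid)
  taxid <- names(cnt)
  rk <- taxon_rank(tree, taxid)
  nm <- taxon_name(tree, taxid)
  label <- ifelse(rk == "species", nm,
                  ifelse(rk == "genus", paste(nm, "undefined species"),
                         paste0("(", rk, ") ", nm)))
  tab <- data.frame(taxid = taxid, label = label, rank = rk,
                    count = as.integer(cnt),
                    relative = 100 * as.integer(cnt) / nrow(cl),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$count, tab$taxid), , drop = FALSE]
  rownames(tab) <- NULL

  rollup <- function(target_rank) {
    anc <- vapply(tab$taxid, function(t) {
      path <- lineage(tree, t)
      hit <- path$taxid[path$rank == target_rank]
      if (length(hit)) hit[1L] else NA_character_
    }, character(1))
    key <- ifelse(is.na(anc), paste0("(above ", target_rank, ")"), anc)
    agg <- tapply(tab$count, key, sum)
    keys <- names(agg)
    lab <- keys
    real <- !grepl("^\\(above", keys)
    lab[real] <- taxon_name(tree, keys[real])
    data.frame(taxid = keys, label = lab, count = as.integer(agg),
               relative = 100 * as.integer(agg) / sum(agg),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(table = tab,
                 rank_tables = list(genus = rollup("genus"),
                                    superkingdom = rollup("superkingdom")),
                 unclassified_count = uncl,
                 total_classified = nrow(cl)),
            class = "taxon_profile")
}

#' @export
print.taxon_profile <- function(x, ...) {
  cat("taxon_profile:", nrow(x$table), "taxa,", x$total_classified,
      "classified reads,", x$unclassified_count, "unclassified\n")
  if (nrow(x$table)) print(utils::head(x$table, 10L))
  invisible(x)
}

#' Correct a profile for species genome size
#'
#' Read counts are proportional to genome size as well as cell abundance;
#' dividing each species' count by its mean genome size and renormalizing
#' (`normalized_i = 100 * (count_i / size_i) / sum_j (count_j / size_j)`)
#' removes that bias. Taxa without an entry in the size table (genus-level
#' bins, higher LCA nodes, unlisted species) use the database-wide mean
#' genome size, with a warning for unlisted species.
#'
#' @param profile a `taxon_profile`
#' @param size_table named numeric vector, species -> mean genome length
#' @return the profile with a `normalized` column added to `table`
#' @export
normalize_by_genome_size <- function(profile, size_table) {
  tab <- profile$table
  if (nrow(tab) == 0L) return(profile)
  if (any(size_table <= 0)) stop("genome sizes must be positive")
  fallback <- mean(size_table)
  size <- rep(fallback, nrow(tab))
  is_sp <- tab$rank == "species"
  hit <- match(tab$label[is_sp], names(size_table))
  if (anyNA(hit))
    warning("species missing from size table (using mean genome size): ",
            paste(tab$label[is_sp][is.na(hit)], collapse = ", "))
  size[is_sp][!is.na(hit)] <- size_table[hit[!is.na(hit)]]
  w <- tab$count / size
  tab$normalized <- 100 * w / sum(w)
  profile$table <- tab
  profile
}

#' End-to-end read profiling against a reference database
#'
#' Subsamples, aligns with the built-in seeded aligner (or consumes a
#' precomputed hit table), classifies and aggregates, then genome-size
#' normalizes. Quality filtering and host depletion are explicit upstream
#' steps ([quality_filter()], [deplete_host()]).
#'
#' @param reads read data.frame
#' @param db a `reference_db`
#' @param params a [classifier_params()]
#' @param seed seed for subsampling
#' @param hits optional precomputed hit table (skips the built-in aligner)
#' @param tree optional `taxonomy_tree` (defaults to one lifted from the
#'   database labels)
#' @return list: `profile` (a `taxon_profile`), `classifications`, `tree`
#' @export
profile_reads <- function(reads, db, params = classifier_params(), seed = 1,
                          hits = NULL, tree = NULL) {
  reads <- subsample_reads(reads, params$sample_size, seed)
  if (is.null(tree)) tree <- taxonomy_from_labels(db$labels)
  if (is.null(hits)) {
    hits <- align_reads(setNames(reads$sequence, reads$read_id),
                        db_sequences(db))
  }
  cls <- classify_reads(hits, tree, db$labels, params,
                        read_ids = reads$read_id)
  prof <- aggregate_profile(cls, tree)
  prof <- normalize_by_genome_size(prof, db$size_table)
  list(profile = prof, classifications = cls, tree = tree)
}

#' Write per-rank profile tables and per-read assignments
#'
#' @param result list from [profile_reads()]
#' @param dir output directory
#' @param prefix file-name prefix
#' @return invisible vector of written paths
#' @export
write_profile <- function(result, dir, prefix = "profile") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) {
    p <- file.path(dir, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- wt(result$profile$table, paste0(prefix, "_species.tsv"))
  for (r in names(result$profile$rank_tables))
    paths <- c(paths, wt(result$profile$rank_tables[[r]],
                         paste0(prefix, "_", r, ".tsv")))
  paths <- c(paths, wt(result$classifications,
                       paste0(prefix, "_assignments.tsv")))
  invisible(paths)
}
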