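#' Curated reference database construction
#'
#' Builds the taxonomically revised, dereplicated reference genome database
#' the classifier aligns against. Curation follows genome-based species
#' delimitation practice: a genome is reassigned to its closest reference
#' genome's species when their average nucleotide identity (ANI) exceeds 94%
#' with both query and subject coverage above 70%; otherwise, if the closest
#' reference shares the declared genus, the declared taxonomy is retained
#' (the species likely has no reference yet); otherwise the genome is flagged
#' unresolved. Near-duplicates (ANI > 99% to their species reference) are
#' dropped, contigs below kingdom-specific length floors (viral 1 kbp,
#' prokaryotic 5 kbp, eukaryotic 12 kbp) are removed, and contigs highly
#' similar to configured host genomes are excised. A per-species mean genome
#' size table supports abundance normalization downstream.
#'
#' @name refdb
NULL

#' Curation parameters
#'
#' @param ani_species_threshold ANI percent above which a genome adopts its
#'   closest reference's species (default 94, strict `>`)
#' @param min_ani_coverage minimum query and subject coverage percent for the
#'   ANI gate (default 70, strict `>`)
#' @param derep_threshold ANI percent above which a genome is dropped as a
#'   near-duplicate of its species reference (default 99, strict `>`)
#' @param min_contig_length named vector of per-kingdom contig length floors
#'   in bases (defaults viral 1000, prokaryotic 5000, eukaryotic 12000;
#'   strictly shorter contigs are removed)
#' @param host_identity_min,host_coverage_min host-decontamination gates:
#'   a contig is removed when a host hit reaches this identity over this
#'   fraction of the contig (defaults 90 and 50)
#' @return a `curation_params` list
#' @export
curation_params <- function(ani_species_threshold = 94,
                            min_ani_coverage = 70,
                            derep_threshold = 99,
                            min_contig_length = c(viral = 1000,
                                                  prokaryotic = 5000,
                                                  eukaryotic = 12000),
                            host_identity_min = 90,
                            host_coverage_min = 50) {
  if (derep_threshold < ani_species_threshold)
    stop("derep_threshold must be >= ani_species_threshold")
  thr <- c(ani_species_threshold, min_ani_coverage, derep_threshold,
           host_identity_min, host_coverage_min)
  if (any(thr <= 0 | thr > 100)) stop("thresholds must lie in (0, 100]")
  structure(list(ani_species_threshold = ani_species_threshold,
                 min_ani_coverage = min_ani_coverage,
                 derep_threshold = derep_threshold,
                 min_contig_length = min_contig_length,
                 host_identity_min = host_identity_min,
                 host_coverage_min = host_coverage_min),
            class = "curation_params")
}

.KINGDOMS <- c("viral", "prokaryotic", "eukaryotic")

#' Assemble an uncurated genome set
#'
#' @param meta data.frame with columns `accession`, `species`, `genus`,
#'   `kingdom` (one of viral/prokaryotic/eukaryotic), `is_reference`
#' @param contigs data.frame with columns `accession`, `contig_id`, `sequence`
#' @return a `genome_set` list with `meta` (plus `total_length`) and `contigs`
#' @export
genome_set <- function(meta, contigs) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  contigs <- as.data.frame(contigs, stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "species", "genus", "kingdom",
                  "is_reference") %in% names(meta)),
            all(c("accession", "contig_id", "sequence") %in% names(contigs)))
  if (anyDuplicated(meta$accession)) stop("duplicate accession in meta")
  bad <- setdiff(unique(meta$kingdom), .KINGDOMS)
  if (length(bad)) stop("unknown kingdom(s): ", paste(bad, collapse = ", "))
  orphan <- setdiff(unique(contigs$accession), meta$accession)
  if (length(orphan))
    stop("contigs cite unknown accession(s): ", paste(orphan, collapse = ", "))
  meta$is_reference <- as.logical(meta$is_reference)
  len <- tapply(nchar(contigs$sequence), contigs$accession, sum)
  meta$total_length <- as.numeric(len[meta$accession])
  meta$total_length[is.na(meta$total_length)] <- 0
  structure(list(meta = meta, contigs = contigs), class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set:", nrow(x$meta), "genomes,", nrow(x$contigs), "contigs,",
      sum(nchar(x$contigs$sequence)), "bases\n")
  invisible(x)
}

.check_ani <- function(ani, accessions) {
  ani <- as.data.frame(ani, stringsAsFactors = FALSE)
  need <- c("query", "subject", "ani", "query_cov", "subject_cov")
  stopifnot(all(need %in% names(ani)))
  unknown <- setdiff(unique(c(ani$query, ani$subject)), accessions)
  if (length(unknown))
    stop("ANI record cites unknown accession(s): ",
         paste(unknown, collapse = ", "))
  rng <- c(ani$ani, ani$query_cov, ani$subject_cov)
  if (length(rng) && (any(rng < 0) || any(rng > 100)))
    stop("ANI and coverages must lie in [0, 100]")
  ani
}

#' Revise genome taxonomy against reference genomes by ANI
#'
#' For each non-reference genome the closest reference is the ANI record with
#' the highest ANI (ties: higher `min(query_cov, subject_cov)`, then
#' lexicographic reference accession). The genome adopts that reference's
#' species and genus when ANI > `ani_species_threshold` and both coverages
#' exceed `min_ani_coverage`; failing that, the declared taxonomy is retained
#' when the closest reference shares the declared genus (`genus_retained`) and
#' flagged `unresolved` otherwise (including genomes with no ANI records).
#' Reference genomes always keep their labels.
#'
#' @param genomes a [genome_set()]
#' @param ani ANI table (data.frame: query, subject, ani, query_cov,
#'   subject_cov); only records whose subject is a reference genome are used
#' @param params a [curation_params()]
#' @return list with `labels` (accession, genus, species) and `change_log`
#'   (accession, old_species, new_species, reason); reasons partition into
#'   ani_reclassified / genus_retained / unresolved
#' @export
revise_taxonomy <- function(genomes, ani, params = curation_params()) {
  meta <- genomes$meta
  ani <- .check_ani(ani, meta$accession)
  refs <- meta$accession[meta$is_reference]
  ani <- ani[ani$subject %in% refs & ani$query != ani$subject, , drop = FALSE]
  labels <- data.frame(accession = meta$accession, genus = meta$genus,
                       species = meta$species, stringsAsFactors = FALSE)
  log_l <- list()
  ref_species <- setNames(meta$species, meta$accession)
  ref_genus <- setNames(meta$genus, meta$accession)
  nonref <- which(!meta$is_reference)
  for (i in nonref) {
    acc <- meta$accession[i]
    rec <- ani[ani$query == acc, , drop = FALSE]
    if (nrow(rec) == 0L) {
      log_l[[length(log_l) + 1L]] <- data.frame(
        accession = acc, old_species = meta$species[i],
        new_species = meta$species[i], reason = "unresolved")
      next
    }
    mincov <- pmin(rec$query_cov, rec$subject_cov)
    ord <- order(-rec$ani, -mincov, rec$subject)
    best <- rec[ord[1L], ]
    if (best$ani > params$ani_species_threshold &&
        best$query_cov > params$min_ani_coverage &&
        best$subject_cov > params$min_ani_coverage) {
      labels$species[i] <- ref_species[[best$subject]]
      labels$genus[i] <- ref_genus[[best$subject]]
      reason <- "ani_reclassified"
    } else if (ref_genus[[best$subject]] == meta$genus[i]) {
      reason <- "genus_retained"
    } else {
      reason <- "unresolved"
    }
    log_l[[length(log_l) + 1L]] <- data.frame(
      accession = acc, old_species = meta$species[i],
      new_species = labels$species[i], reason = reason)
  }
  change_log <- if (length(log_l)) do.call(rbind, log_l) else
    data.frame(accession = character(0), old_species = character(0),
               new_species = character(0), reason = character(0))
  list(labels = labels, change_log = change_log)
}

#' Drop near-duplicate genomes (ANI above threshold to species reference)
#'
#' A non-reference genome is removed iff an ANI record (either direction)
#' links it to a reference genome of its own (revised) species with ANI
#' strictly above `derep_threshold`. Reference genomes, and genomes whose
#' species has no reference, are always retained.
#'
#' @param genomes a [genome_set()]
#' @param labels revised labels from [revise_taxonomy()]
#' @param ani ANI table
#' @param params a [curation_params()]
#' @return character vector of retained accessions
#' @export
dereplicate <- function(genomes, labels, ani, params = curation_params()) {
  meta <- genomes$meta
  ani <- .check_ani(ani, meta$accession)
  lab_species <- setNames(labels$species, labels$accession)
  refs <- meta$accession[meta$is_reference]
  drop <- logical(nrow(meta))
  for (i in which(!meta$is_reference)) {
    acc <- meta$accession[i]
    sp_refs <- refs[lab_species[refs] == lab_species[[acc]]]
    if (length(sp_refs) == 0L) next
    rec <- ani[(ani$query == acc & ani$subject %in% sp_refs) |
               (ani$subject == acc & ani$query %in% sp_refs), , drop = FALSE]
    if (nrow(rec) && max(rec$ani) > params$derep_threshold) drop[i] <- TRUE
  }
  meta$accession[!drop]
}

.subset_genome_set <- function(genomes, accessions) {
  genome_set(genomes$meta[genomes$meta$accession %in% accessions,
                          setdiff(names(genomes$meta), "total_length"),
                          drop = FALSE],
             genomes$contigs[genomes$contigs$accession %in% accessions, ,
                             drop = FALSE])
}

#' Remove contigs below the kingdom-specific length floor
#'
#' Contigs strictly shorter than the floor for their genome's kingdom are
#' removed; genomes left without contigs are dropped from the set.
#'
#' @param genomes a [genome_set()]
#' @param params a [curation_params()]
#' @return a filtered [genome_set()] with `total_length` recomputed
#' @export
filter_contigs_by_length <- function(genomes, params = curation_params()) {
  floors <- params$min_contig_length[
    genomes$meta$kingdom[match(genomes$contigs$accession,
                               genomes$meta$accession)]]
  keep <- nchar(genomes$contigs$sequence) >= unname(floors)
  contigs <- genomes$contigs[keep, , drop = FALSE]
  survivors <- intersect(genomes$meta$accession, unique(contigs$accession))
  genome_set(genomes$meta[genomes$meta$accession %in% survivors,
                          setdiff(names(genomes$meta), "total_length"),
                          drop = FALSE],
             contigs)
}

#' Remove contigs with high identity to host genomes
#'
#' A contig is removed iff some host hit reaches `host_identity_min` percent
#' identity over at least `host_coverage_min` percent of the contig. Hits use
#' the standard layout with `qseqid = "accession|contig_id"` and `qcovs` the
#' percent of the contig aligned.
#'
#' @param genomes a [genome_set()]
#' @param host_hits data.frame of contig-vs-host hits (may have zero rows)
#' @param params a [curation_params()]
#' @return a decontaminated [genome_set()]
#' @export
remove_host_contigs <- function(genomes, host_hits,
                                params = curation_params()) {
  if (is.null(host_hits) || nrow(host_hits) == 0L) return(genomes)
  keys <- paste(genomes$contigs$accession, genomes$contigs$contig_id,
                sep = "|")
  unknown <- setdiff(unique(host_hits$qseqid), keys)
  if (length(unknown))
    stop("host hits cite unknown contig(s): ", paste(unknown, collapse = ", "))
  flagged <- unique(host_hits$qseqid[
    host_hits$pident >= params$host_identity_min &
    host_hits$qcovs >= params$host_coverage_min])
  contigs <- genomes$contigs[!(keys %in% flagged), , drop = FALSE]
  survivors <- intersect(genomes$meta$accession, unique(contigs$accession))
  genome_set(genomes$meta[genomes$meta$accession %in% survivors,
                          setdiff(names(genomes$meta), "total_length"),
                          drop = FALSE],
             contigs)
}

#' Per-species mean genome size table
#'
#' @param genomes a curated [genome_set()]
#' @param labels revised labels (accession, genus, species)
#' @return named numeric vector: species -> arithmetic mean of retained
#'   genomes' total lengths
#' @export
build_size_table <- function(genomes, labels) {
  sp <- labels$species[match(genomes$meta$accession, labels$accession)]
  m <- tapply(genomes$meta$total_length, sp, mean)
  setNames(as.numeric(m), names(m))
}

#' Run the full curation pipeline
#'
#' revise -> dereplicate -> contig length filter -> host decontamination ->
#' size table. The order of the two contig-level filters is fixed with the
#' length filter first; both are reported in the change log.
#'
#' @param genomes a [genome_set()]
#' @param ani ANI table
#' @param params a [curation_params()]
#' @param host_hits optional contig-vs-host hits (see [remove_host_contigs()])
#' @return a `reference_db` list: `genomes` (curated [genome_set()]), `labels`
#'   (with kingdom and species taxid), `size_table`, `change_log`, `params`
#' @export
curate_reference_db <- function(genomes, ani, params = curation_params(),
                                host_hits = NULL) {
  rev <- revise_taxonomy(genomes, ani, params)
  retained <- dereplicate(genomes, rev$labels, ani, params)
  g <- .subset_genome_set(genomes, retained)
  g <- filter_contigs_by_length(g, params)
  g <- remove_host_contigs(g, host_hits, params)
  labels <- rev$labels[rev$labels$accession %in% g$meta$accession, ,
                       drop = FALSE]
  labels$kingdom <- g$meta$kingdom[match(labels$accession, g$meta$accession)]
  labels$taxid <- paste0("s__", labels$species)
  structure(list(genomes = g, labels = labels,
                 size_table = build_size_table(g, labels),
                 change_log = rev$change_log, params = params),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("reference_db:", nrow(x$genomes$meta), "genomes,",
      length(x$size_table), "species,",
      nrow(x$genomes$contigs), "contigs\n")
  invisible(x)
}

#' Reference sequences of a database as a named vector
#'
#' Names follow the `accession|contig_id` convention the aligners and
#' classifier expect.
#'
#' @param db a `reference_db`
#' @return named character vector of contig sequences
#' @export
db_sequences <- function(db) {
  setNames(db$genomes$contigs$sequence,
           paste(db$genomes$contigs$accession, db$genomes$contigs$contig_id,
                 sep = "|"))
}

#' Write a reference database to a directory
#'
#' Emits `contigs.fasta` (headers `accession|contig_id`), `meta.tsv`,
#' `labels.tsv`, `size_table.tsv` and `change_log.tsv`; the companion
#' [read_reference_db()] restores an equal object.
#'
#' @param db a `reference_db`
#' @param dir output directory
#' @return invisible `dir`
#' @export
write_reference_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(db_sequences(db), file.path(dir, "contigs.fasta"))
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(db$genomes$meta[, c("accession", "species", "genus", "kingdom",
                         "is_reference")], "meta.tsv")
  wt(db$labels, "labels.tsv")
  wt(data.frame(species = names(db$size_table),
                mean_total_length = unname(db$size_table)), "size_table.tsv")
  wt(db$change_log, "change_log.tsv")
  invisible(dir)
}

#' Read a reference database written by [write_reference_db()]
#' @param dir database directory
#' @return a `reference_db`
#' @export
read_reference_db <- function(dir) {
  rt <- function(f) utils::read.delim(file.path(dir, f),
                                      colClasses = "character")
  meta <- rt("meta.tsv")
  meta$is_reference <- as.logical(meta$is_reference)
  seqs <- if (file.size(file.path(dir, "contigs.fasta")) > 0)
    read_fasta(file.path(dir, "contigs.fasta")) else character(0)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  contigs <- data.frame(
    accession = vapply(parts, `[`, "", 1L),
    contig_id = vapply(parts, `[`, "", 2L),
    sequence = unname(seqs), stringsAsFactors = FALSE)
  st <- rt("size_table.tsv")
  labels <- rt("labels.tsv")
  structure(list(genomes = genome_set(meta, contigs), labels = labels,
                 size_table = setNames(as.numeric(st$mean_total_length),
                                       st$species),
                 change_log = rt("change_log.tsv"),
                 params = curation_params()),
            class = "reference_db")
}

#' Build a reference database directly from simulated genomes
#'
#' Convenience for benchmarks: wraps each simulated genome as a single-contig
#' prokaryotic genome whose species name is the simulated species, skipping
#' ANI curation (each genome is its own species reference).
#'
#' @param genomes named character vector of genome sequences (names = species)
#' @param kingdom kingdom tag applied to all genomes (default "prokaryotic")
#' @return a `reference_db`
#' @export
db_from_genomes <- function(genomes, kingdom = "prokaryotic") {
  acc <- sprintf("SIM%04d", seq_along(genomes))
  meta <- data.frame(accession = acc, species = names(genomes),
                     genus = paste0("Genus_", names(genomes)),
                     kingdom = kingdom, is_reference = TRUE,
                     stringsAsFactors = FALSE)
  contigs <- data.frame(accession = acc, contig_id = "c1",
                        sequence = unname(genomes), stringsAsFactors = FALSE)
  gs <- genome_set(meta, contigs)
  labels <- meta[, c("accession", "genus", "species", "kingdom")]
  labels$taxid <- paste0("s__", labels$species)
  structure(list(genomes = gs, labels = labels,
                 size_table = build_size_table(gs, labels),
                 change_log = data.frame(accession = character(0),
                                         old_species = character(0),
                                         new_species = character(0),
                                         reason = character(0)),
                 params = curation_params()),
            class = "reference_db")
}
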