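#' Synthetic data generators with ground-truth manifests
#'
#' Seeded simulators for genomes, 150-bp Illumina paired-end reads
#' (substitution errors, WGSIM-style base error rate 0.02) and 8-kbp
#' Nanopore-like long reads (error rate 0.003, split evenly between
#' substitutions, insertions and deletions). Every emitted read carries a
#' truth-manifest row (source species, genome, coordinates, strand), and each
#' data set carries its expected relative-abundance profile, which drives the
#' DExA and confusion benchmarks.
#'
#' @name simdata
NULL

.revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Specify a simulated community
#'
#' @param species data.frame with columns `name`, `length` (genome bases),
#'   `gc` (fraction), `reads` (reads to emit for this species; paired-end
#'   generation requires an even count)
#' @param read_length short-read length (default 150)
#' @param base_error_rate short-read substitution rate (default 0.02)
#' @param long_read_length long-read length, fixed (default 8000)
#' @param long_read_error_rate long-read edit rate (default 0.003)
#' @param insert_mean,insert_sd paired-end insert size model (default 400/40)
#' @param seed integer seed controlling every random draw
#' @return a `sim_spec` list
#' @export
sim_spec <- function(species, read_length = 150, base_error_rate = 0.02,
                     long_read_length = 8000, long_read_error_rate = 0.003,
                     insert_mean = 400, insert_sd = 40, seed = 1) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "length", "reads") %in% names(species)))
  if (is.null(species$gc)) species$gc <- 0.5
  if (anyDuplicated(species$name)) stop("duplicate species names")
  if (any(species$reads <= 0)) stop("abundances (read counts) must be positive")
  if (base_error_rate < 0 || base_error_rate >= 1 ||
      long_read_error_rate < 0 || long_read_error_rate >= 1)
    stop("error rates must lie in [0, 1)")
  structure(list(species = species, read_length = read_length,
                 base_error_rate = base_error_rate,
                 long_read_length = long_read_length,
                 long_read_error_rate = long_read_error_rate,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a random genome
#'
#' I.i.d. bases with P(G) + P(C) = `gc` (split evenly within each pair).
#'
#' @param length genome length in bases (>= 1000)
#' @param gc GC fraction in `[0, 1]`
#' @param seed optional seed; fixed seed gives an identical sequence
#' @return a single character string of A/C/G/T
#' @export
simulate_genome <- function(length, gc = 0.5, seed = NULL) {
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  if (length < 1000) stop("genome length must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), length, replace = TRUE, prob = probs),
        collapse = "")
}

#' Simulate all genomes of a community spec
#' @param spec a [sim_spec()]
#' @return named character vector, one genome per species
#' @export
simulate_genomes <- function(spec) {
  set.seed(spec$seed)
  out <- vapply(seq_len(nrow(spec$species)), function(i) {
    simulate_genome(spec$species$length[i], spec$species$gc[i])
  }, character(1))
  names(out) <- spec$species$name
  out
}

# vectorized substitution errors over a character vector of reads;
# returns the mutated reads. Bases other than ACGT are left untouched.
.apply_substitutions <- function(reads, p) {
  if (p <= 0 || length(reads) == 0L) return(reads)
  lens <- nchar(reads)
  x <- charToRaw(paste(reads, collapse = ""))
  hit <- which(stats::runif(length(x)) < p)
  if (length(hit)) {
    code <- integer(length(hit))
    cur <- x[hit]
    code[cur == charToRaw("A")] <- 0L
    code[cur == charToRaw("C")] <- 1L
    code[cur == charToRaw("G")] <- 2L
    code[cur == charToRaw("T")] <- 3L
    valid <- cur %in% charToRaw("ACGT")
    shift <- sample.int(3L, length(hit), replace = TRUE)
    newcode <- (code + shift) %% 4L
    bases <- charToRaw("ACGT")
    x[hit[valid]] <- bases[newcode[valid] + 1L]
  }
  s <- rawToChar(x)
  ends <- cumsum(lens)
  substring(s, ends - lens + 1L, ends)
}

#' Simulate Illumina paired-end reads with a truth manifest
#'
#' For each species exactly the specified read count is emitted (half as
#' forward mates, half as reverse mates of the same fragments). Fragments are
#' drawn uniformly over genome positions and strands; each base is substituted
#' independently at `base_error_rate`; quality strings are constant Q30 (truth
#' lives in the manifest, not in qualities).
#'
#' @param spec a [sim_spec()]; per-species `reads` must be even
#' @param genomes optional named genome vector (defaults to
#'   [simulate_genomes()] under the spec's seed)
#' @return a `sim_reads` list: `reads` (read_id, sequence, quality, mate,
#'   pair_id), `manifest` (read_id, species, start, end, strand, mate),
#'   `expected_profile` (named percent vector summing to 100), `genomes`,
#'   `spec`, `paired = TRUE`
#' @export
simulate_illumina <- function(spec, genomes = NULL) {
  if (is.null(genomes)) genomes <- simulate_genomes(spec)
  set.seed(spec$seed + 1L)
  L <- spec$read_length
  sp <- spec$species
  if (any(sp$reads %% 2 != 0))
    stop("paired-end simulation needs an even read count per species")
  reads_l <- vector("list", nrow(sp))
  man_l <- vector("list", nrow(sp))
  for (i in seq_len(nrow(sp))) {
    g <- genomes[[sp$name[i]]]
    glen <- nchar(g)
    npair <- sp$reads[i] / 2
    if (glen < spec$insert_mean)
      stop("genome for ", sp$name[i], " is shorter than the mean insert size")
    ins <- round(stats::rnorm(npair, spec$insert_mean, spec$insert_sd))
    ins <- pmin(pmax(ins, L), glen)
    fstart <- 1L + floor(stats::runif(npair) * (glen - ins + 1))
    fend <- fstart + ins - 1L
    fwd <- stats::runif(npair) < 0.5
    frag <- substring(g, fstart, fend)
    frag[!fwd] <- .revcomp(frag[!fwd])
    r1 <- substr(frag, 1L, L)
    r2 <- .revcomp(substring(frag, ins - L + 1L, ins))
    r1 <- .apply_substitutions(r1, spec$base_error_rate)
    r2 <- .apply_substitutions(r2, spec$base_error_rate)
    tag <- gsub("[^A-Za-z0-9]+", "_", sp$name[i])
    pid <- sprintf("%s_p%06d", tag, seq_len(npair))
    # per-mate source coordinates on the genome
    m1_start <- ifelse(fwd, fstart, fend - L + 1L)
    m1_end <- m1_start + L - 1L
    m1_strand <- ifelse(fwd, "+", "-")
    m2_start <- ifelse(fwd, fend - L + 1L, fstart)
    m2_end <- m2_start + L - 1L
    m2_strand <- ifelse(fwd, "-", "+")
    reads_l[[i]] <- data.frame(
      read_id = c(paste0(pid, "/1"), paste0(pid, "/2")),
      sequence = c(r1, r2),
      quality = strrep("?", L),
      mate = rep(c(1L, 2L), each = npair),
      pair_id = c(pid, pid),
      stringsAsFactors = FALSE)
    man_l[[i]] <- data.frame(
      read_id = c(paste0(pid, "/1"), paste0(pid, "/2")),
      species = sp$name[i],
      start = c(m1_start, m2_start), end = c(m1_end, m2_end),
      strand = c(m1_strand, m2_strand),
      mate = rep(c(1L, 2L), each = npair),
      stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, reads_l)
  manifest <- do.call(rbind, man_l)
  expected <- 100 * sp$reads / sum(sp$reads)
  names(expected) <- sp$name
  structure(list(reads = reads, manifest = manifest,
                 expected_profile = expected, genomes = genomes,
                 spec = spec, paired = TRUE),
            class = "sim_reads")
}

# apply substitution/insertion/deletion edits to one sequence; op types are
# drawn uniformly. Returns the edited string.
.apply_edits <- function(seq, nops) {
  if (nops == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sort(sample.int(length(chars), min(nops, length(chars))),
              decreasing = TRUE)
  ops <- sample(c("sub", "ins", "del"), length(pos), replace = TRUE)
  bases <- c("A", "C", "G", "T")
  for (j in seq_along(pos)) {
    p <- pos[j]
    if (ops[j] == "sub") {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    } else if (ops[j] == "ins") {
      chars <- append(chars, sample(bases, 1L), after = p)
    } else {
      chars <- chars[-p]
    }
  }
  paste(chars, collapse = "")
}

#' Simulate Nanopore-like long reads with a truth manifest
#'
#' Fixed-length reads (default 8 kbp) drawn uniformly over positions and
#' strands, with edits applied at `long_read_error_rate`, split evenly among
#' substitutions, insertions and deletions (long-read errors are
#' indel-dominated, unlike the substitution-only short-read model).
#'
#' @inheritParams simulate_illumina
#' @return a `sim_reads` list as for [simulate_illumina()], `paired = FALSE`
#' @export
simulate_nanopore <- function(spec, genomes = NULL) {
  if (is.null(genomes)) genomes <- simulate_genomes(spec)
  set.seed(spec$seed + 2L)
  L <- spec$long_read_length
  sp <- spec$species
  reads_l <- vector("list", nrow(sp))
  man_l <- vector("list", nrow(sp))
  for (i in seq_len(nrow(sp))) {
    g <- genomes[[sp$name[i]]]
    glen <- nchar(g)
    if (glen < L)
      stop("genome for ", sp$name[i], " is shorter than the long-read length")
    n <- sp$reads[i]
    start <- 1L + floor(stats::runif(n) * (glen - L + 1))
    fwd <- stats::runif(n) < 0.5
    seqs <- substring(g, start, start + L - 1L)
    seqs[!fwd] <- .revcomp(seqs[!fwd])
    nops <- stats::rbinom(n, L, spec$long_read_error_rate)
    for (j in seq_len(n)) seqs[j] <- .apply_edits(seqs[j], nops[j])
    tag <- gsub("[^A-Za-z0-9]+", "_", sp$name[i])
    rid <- sprintf("%s_long%06d", tag, seq_len(n))
    reads_l[[i]] <- data.frame(
      read_id = rid, sequence = seqs,
      quality = strrep("?", nchar(seqs)),
      mate = 0L, pair_id = rid, stringsAsFactors = FALSE)
    man_l[[i]] <- data.frame(
      read_id = rid, species = sp$name[i],
      start = start, end = start + L - 1L,
      strand = ifelse(fwd, "+", "-"), mate = 0L,
      stringsAsFactors = FALSE)
  }
  expected <- 100 * sp$reads / sum(sp$reads)
  names(expected) <- sp$name
  structure(list(reads = do.call(rbind, reads_l),
                 manifest = do.call(rbind, man_l),
                 expected_profile = expected, genomes = genomes,
                 spec = spec, paired = FALSE),
            class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("sim_reads:", nrow(x$reads), "reads from",
      nrow(x$spec$species), "species",
      if (x$paired) "(paired-end)" else "(long reads)", "\n")
  invisible(x)
}

#' Fabricate an ANI table for database-curation tests
#'
#' Emits planted (query, subject, ANI, coverage) relations in the TSV layout
#' [revise_taxonomy()] consumes, standing in for a precomputed all-vs-all ANI
#' matrix.
#'
#' @param accessions character vector of known genome accessions
#' @param relations data.frame with columns `query`, `subject`, `ani`,
#'   `query_cov`, `subject_cov`
#' @param symmetric also emit each relation with query/subject (and the two
#'   coverages) swapped
#' @param path optional file to write the TSV to
#' @return the ANI data.frame (invisibly when `path` is given)
#' @export
make_ani_fixture <- function(accessions, relations, symmetric = FALSE,
                             path = NULL) {
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  need <- c("query", "subject", "ani", "query_cov", "subject_cov")
  stopifnot(all(need %in% names(relations)))
  unknown <- setdiff(unique(c(relations$query, relations$subject)), accessions)
  if (length(unknown))
    stop("ANI relations cite unknown accession(s): ",
         paste(unknown, collapse = ", "))
  out <- relations[, need]
  if (symmetric && nrow(relations)) {
    sw <- data.frame(query = relations$subject, subject = relations$query,
                     ani = relations$ani, query_cov = relations$subject_cov,
                     subject_cov = relations$query_cov,
                     stringsAsFactors = FALSE)
    out <- unique(rbind(out, sw))
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Write a simulated read set to FASTQ plus manifest/profile sidecars
#'
#' @param sim a `sim_reads` object
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix (default "sim")
#' @return invisible character vector of written paths
#' @export
write_sim_output <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (sim$paired) {
    for (m in 1:2) {
      p <- file.path(dir, sprintf("%s_R%d.fastq", prefix, m))
      write_fastq(sim$reads[sim$reads$mate == m, ], p)
      paths <- c(paths, p)
    }
  } else {
    p <- file.path(dir, paste0(prefix, ".fastq"))
    write_fastq(sim$reads, p)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, paste0(prefix, "_manifest.tsv"))
  utils::write.table(sim$manifest, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ep <- file.path(dir, paste0(prefix, "_expected_profile.tsv"))
  utils::write.table(
    data.frame(species = names(sim$expected_profile),
               expected_relative = unname(sim$expected_profile)),
    ep, sep = "\t", quote = FALSE, row.names = FALSE)
  sp <- file.path(dir, paste0(prefix, "_spec.json"))
  jsonlite::write_json(unclass(sim$spec), sp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp, ep, sp))
}
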