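# shared fixtures and independent oracles, built in code

# small fixed taxonomy: 2 superkingdoms, 2 genera, 4 species
fixture_tree <- function() {
  build_taxonomy(data.frame(
    taxid = c("root", "k_bac", "k_vir", "g_esch", "g_lact",
              "s_coli", "s_ferg", "s_casei", "v_phage1", "v_phage2"),
    parent_taxid = c("root", "root", "root", "k_bac", "k_bac",
                     "g_esch", "g_esch", "g_lact", "k_vir", "k_vir"),
    rank = c("root", "superkingdom", "superkingdom", "genus", "genus",
             "species", "species", "species", "species", "species"),
    name = c("root", "Bacteria", "Viruses", "Escherichia", "Lacticaseibacillus",
             "Escherichia coli", "Escherichia fergusonii",
             "Lacticaseibacillus casei", "Phage one", "Phage two"),
    stringsAsFactors = FALSE))
}

# random tree with the canonical ranks; children attach to any shallower node
random_tree_records <- function(n, seed) {
  set.seed(seed)
  ranks <- c("root", "superkingdom", "phylum", "class", "order",
             "family", "genus", "species")
  taxid <- c("root", paste0("n", seq_len(n - 1)))
  rank <- c("root", character(n - 1))
  parent <- c("root", character(n - 1))
  rank_num <- c(1L, integer(n - 1))
  for (i in 2:n) {
    eligible <- which(rank_num[seq_len(i - 1)] < 8L)
    p <- eligible[sample.int(length(eligible), 1)]
    lo <- rank_num[p] + 1L
    r <- if (lo == 8L) 8L else sample(lo:8, 1)
    parent[i] <- taxid[p]
    rank[i] <- ranks[r]
    rank_num[i] <- r
  }
  data.frame(taxid = taxid, parent_taxid = parent, rank = rank,
             name = taxid, stringsAsFactors = FALSE)
}

# independent LCA oracle: intersect full root-to-node paths walked on the
# raw record table (no taxonomy_tree methods involved)
oracle_lca <- function(records, taxids) {
  walk <- function(t) {
    path <- t
    while (t != "root") {
      t <- records$parent_taxid[records$taxid == t]
      path <- c(t, path)
    }
    path
  }
  paths <- lapply(taxids, walk)
  common <- Reduce(function(a, b) {
    k <- min(length(a), length(b))
    same <- a[seq_len(k)] == b[seq_len(k)]
    a[seq_len(if (all(same)) k else which(!same)[1] - 1)]
  }, paths)
  common[length(common)]
}

# independent score-only Smith-Waterman in plain R (linear gap)
oracle_sw_score <- function(q, s, match = 1, mismatch = -1, gap = -2) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  H <- matrix(0L, n + 1, m + 1)
  best <- 0L
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sub <- H[i, j] + if (qc[i] == sc[j]) match else mismatch
    H[i + 1, j + 1] <- max(0L, sub, H[i, j + 1] + gap, H[i + 1, j] + gap)
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

revcomp_chr <- function(x) chartr("ACGT", "TGCA",
                                  paste(rev(strsplit(x, "")[[1]]),
                                        collapse = ""))

# one-row hit in the standard layout, with sensible defaults
make_hit <- function(qseqid = "r1", sseqid = "ACC1|c1", pident = 99,
                     length = 150, evalue = 1e-30, bitscore = 200,
                     qcovs = 100, qstart = 1, qend = 150,
                     sstart = 1, send = 150) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = length, mismatch = round(length * (100 - pident) / 100),
             gapopen = 0L, qstart = qstart, qend = qend, sstart = sstart,
             send = send, evalue = evalue, bitscore = bitscore,
             qcovs = qcovs, stringsAsFactors = FALSE)
}

# labels table matching fixture_tree()
fixture_labels <- function() {
  data.frame(
    accession = c("ACC1", "ACC2", "ACC3", "VIR1", "VIR2"),
    genus = c("Escherichia", "Escherichia", "Lacticaseibacillus",
              "Phage one", "Phage two"),
    species = c("Escherichia coli", "Escherichia fergusonii",
                "Lacticaseibacillus casei", "Phage one", "Phage two"),
    kingdom = c("prokaryotic", "prokaryotic", "prokaryotic",
                "viral", "viral"),
    stringsAsFactors = FALSE)
}

# tree whose species taxids follow the s__/g__ convention of the labels
fixture_label_tree <- function() taxonomy_from_labels(fixture_labels())

# genome set with planted curation cases
fixture_genome_set <- function() {
  set.seed(42)
  mk <- function(n) random_dna(n)
  meta <- data.frame(
    accession = c("REF_A", "REF_B", "G1", "G2", "G3", "G4", "V1", "E1"),
    species = c("Alpha primus", "Beta secundus", "Alpha mislabeled",
                "Alpha primus", "Gamma novus", "Delta orphan",
                "Virus unus", "Fungus unus"),
    genus = c("Alpha", "Beta", "Alpha", "Alpha", "Gamma", "Delta",
              "Virus", "Fungus"),
    kingdom = c(rep("prokaryotic", 6), "viral", "eukaryotic"),
    is_reference = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  contigs <- data.frame(
    accession = c("REF_A", "REF_B", "G1", "G2", "G3", "G4",
                  "V1", "V1", "E1", "E1"),
    contig_id = c("c1", "c1", "c1", "c1", "c1", "c1",
                  "c1", "c2", "c1", "c2"),
    sequence = c(mk(6000), mk(7000), mk(6500), mk(6200), mk(5800), mk(5500),
                 mk(1000), mk(900), mk(12000), mk(11999)),
    stringsAsFactors = FALSE)
  genome_set(meta, contigs)
}

# ANI table planting: G1 reclassifies to REF_A (96.2/80/78); G2 is a near
# duplicate of REF_A (99.5); G3 fails coverage (96 ANI, 60 qcov) but shares
# no reference genus -> unresolved; G4 closest ref 90 ANI, different genus,
# but same-genus retention is exercised separately
fixture_ani <- function() {
  data.frame(
    query = c("G1", "G2", "G3", "G4"),
    subject = c("REF_A", "REF_A", "REF_A", "REF_B"),
    ani = c(96.2, 99.5, 96, 90),
    query_cov = c(80, 95, 60, 75),
    subject_cov = c(78, 96, 75, 72),
    stringsAsFactors = FALSE)
}

# independent full-DP local alignment with traceback (score, matches, length);
# same deterministic tie policy as the package aligner, written separately
oracle_sw_full <- function(q, s, match = 1, mismatch = -1, gap = -2) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  H <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sub <- H[i, j] + if (qc[i] == sc[j]) match else mismatch
    H[i + 1, j + 1] <- max(0L, sub, H[i, j + 1] + gap, H[i + 1, j] + gap)
  }
  best <- max(H)
  if (best == 0L) return(list(score = 0L, matches = 0L, len = 0L))
  hit <- which(H == best, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  i <- hit[1, 1] - 1L; j <- hit[1, 2] - 1L
  matches <- 0L; len <- 0L
  while (i > 0 && j > 0 && H[i + 1, j + 1] > 0) {
    d <- H[i, j] + if (qc[i] == sc[j]) match else mismatch
    if (H[i + 1, j + 1] == d) {
      matches <- matches + (qc[i] == sc[j]); len <- len + 1L
      i <- i - 1L; j <- j - 1L
    } else if (H[i + 1, j + 1] == H[i, j + 1] + gap) {
      len <- len + 1L; i <- i - 1L
    } else {
      len <- len + 1L; j <- j - 1L
    }
  }
  list(score = best, matches = matches, len = len)
}

# recover the raw +1/-1/-2 score from a synthetic bit score
raw_score_from_bits <- function(bits) round((bits * log(2) + log(0.621)) / 1.33)
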