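make_read <- function(id, len = 150, q = 30, mate = 0L, pair = id) {
  data.frame(read_id = id, sequence = random_dna(len),
             quality = strrep(rawToChar(as.raw(q + 33)), len),
             mate = mate, pair_id = pair, stringsAsFactors = FALSE)
}

test_that("quality filter applies the mean-Phred and length floors", {
  set.seed(1)
  ok <- make_read("ok")                      # 150 bp, Q30
  short <- make_read("short", len = 149)     # one base under the floor
  # mean 24.9: Q25 except 15 bases at Q24 -> mean 24.9 exactly
  lowq <- make_read("lowq")
  lowq$quality <- paste0(strrep(rawToChar(as.raw(25 + 33)), 135),
                         strrep(rawToChar(as.raw(24 + 33)), 15))
  mean_q <- mean(utf8ToInt(lowq$quality) - 33)
  expect_equal(mean_q, 24.9)
  res <- quality_filter(rbind(ok, short, lowq))
  expect_equal(res$reads$read_id, "ok")
  expect_equal(res$stats$removed_length, 1L)
  expect_equal(res$stats$removed_quality, 1L)
  # boundary keeps: exactly Q25 at exactly 150 bp
  q25 <- make_read("q25", q = 25)
  expect_equal(quality_filter(q25)$reads$read_id, "q25")
  bad <- ok; bad$quality <- substr(bad$quality, 1, 10)
  expect_error(quality_filter(bad), "mismatch")
})

test_that("paired mode drops both mates when either fails", {
  set.seed(2)
  r1 <- make_read("p1/1", mate = 1L, pair = "p1")
  r2 <- make_read("p1/2", len = 140, mate = 2L, pair = "p1")  # fails
  r3 <- make_read("p2/1", mate = 1L, pair = "p2")
  r4 <- make_read("p2/2", mate = 2L, pair = "p2")
  res <- quality_filter(rbind(r1, r2, r3, r4))
  expect_setequal(res$reads$read_id, c("p2/1", "p2/2"))
})

test_that("host depletion removes only confidently host-matching reads", {
  set.seed(3)
  reads <- rbind(make_read("h1"), make_read("h2"), make_read("clean"))
  hits <- rbind(
    make_hit(qseqid = "h1", pident = 99, qcovs = 100, evalue = 1e-40),
    make_hit(qseqid = "h2", pident = 99, qcovs = 50, evalue = 1e-40))
  out <- deplete_host(reads, hits)
  expect_setequal(out$read_id, c("h2", "clean"))  # coverage gate spares h2
  expect_identical(deplete_host(reads, NULL), reads)
})

test_that("subsampling is seed-reproducible, keeps pairs together and is uniform", {
  set.seed(4)
  reads <- do.call(rbind, lapply(1:40, function(i)
    make_read(paste0("r", i))))
  s1 <- subsample_reads(reads, 10, seed = 9)
  s2 <- subsample_reads(reads, 10, seed = 9)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 10L)
  expect_equal(nrow(subsample_reads(reads, 1000, seed = 1)), 40L)

  paired <- do.call(rbind, lapply(1:10, function(i) rbind(
    make_read(paste0("p", i, "/1"), mate = 1L, pair = paste0("p", i)),
    make_read(paste0("p", i, "/2"), mate = 2L, pair = paste0("p", i)))))
  sp <- subsample_reads(paired, 8, seed = 2)
  expect_equal(nrow(sp), 8L)
  expect_true(all(table(sp$pair_id) == 2L))

  freq <- rowMeans(vapply(seq_len(400), function(s)
    reads$read_id %in% subsample_reads(reads, 10, seed = s)$read_id,
    logical(40)))
  expect_true(all(abs(freq - 0.25) < 0.1))  # ~4 binomial sigma
})

test_that("classify_read follows the species/LCA/genus/unclassified rule", {
  tree <- fixture_label_tree()
  labels <- fixture_labels()
  p <- classifier_params()

  one <- classify_read(make_hit(pident = 96), tree, labels, p)
  expect_equal(one$assigned_rank, "species")
  expect_equal(one$species_label, "Escherichia coli")
  expect_equal(one$method, "best_hit")

  # equal best hits to two congeneric species -> genus via LCA
  two <- classify_read(rbind(
    make_hit(pident = 97, sseqid = "ACC1|c1"),
    make_hit(pident = 97, sseqid = "ACC2|c1")), tree, labels, p)
  expect_equal(two$assigned_rank, "genus")
  expect_equal(two$taxid, "g__Escherichia")
  expect_equal(two$method, "lca")
  expect_equal(two$species_label, "undefined species")

  # equal best hits across genera -> LCA above genus
  far <- classify_read(rbind(
    make_hit(pident = 97, sseqid = "ACC1|c1"),
    make_hit(pident = 97, sseqid = "ACC3|c1")), tree, labels, p)
  expect_equal(far$assigned_rank, "higher")

  # 60% identity -> genus of best hit as undefined species
  mid <- classify_read(make_hit(pident = 60), tree, labels, p)
  expect_equal(mid$assigned_rank, "genus")
  expect_equal(mid$species_label, "undefined species")

  # below the genus floor -> unclassified
  low <- classify_read(make_hit(pident = 15), tree, labels, p)
  expect_equal(low$assigned_rank, "unclassified")
  expect_true(is.na(low$taxid))

  # identity exactly at the species cutoff stays genus-level (strict >)
  edge <- classify_read(make_hit(pident = 94), tree, labels, p)
  expect_equal(edge$assigned_rank, "genus")

  expect_error(classify_read(make_hit(sseqid = "GHOST|c1"), tree, labels, p),
               "absent from labels")
})

test_that("viral ties skip LCA and take the highest bit score", {
  tree <- fixture_label_tree()
  labels <- fixture_labels()
  p <- classifier_params()
  vir <- classify_read(rbind(
    make_hit(pident = 98, sseqid = "VIR1|c1", bitscore = 180),
    make_hit(pident = 98, sseqid = "VIR2|c1", bitscore = 220)),
    tree, labels, p)
  expect_equal(vir$method, "viral_best_hit")
  expect_equal(vir$species_label, "Phage two")
  expect_equal(vir$assigned_rank, "species")
  # with the switch off, viral ties go through LCA like everything else
  p2 <- classifier_params(viral_lca_disabled = FALSE)
  vir2 <- classify_read(rbind(
    make_hit(pident = 98, sseqid = "VIR1|c1", bitscore = 180),
    make_hit(pident = 98, sseqid = "VIR2|c1", bitscore = 220)),
    tree, labels, p2)
  expect_equal(vir2$method, "lca")
  # a mixed viral/non-viral tie also resolves by LCA
  mixed <- classify_read(rbind(
    make_hit(pident = 98, sseqid = "VIR1|c1"),
    make_hit(pident = 98, sseqid = "ACC1|c1")), tree, labels, p)
  expect_equal(mixed$method, "lca")
})

test_that("classification is invariant to hit order and monotone in the species cutoff", {
  tree <- fixture_label_tree()
  labels <- fixture_labels()
  set.seed(21)
  hits <- do.call(rbind, lapply(seq_len(12), function(i)
    make_hit(pident = sample(c(92, 95, 97), 1),
             sseqid = sample(c("ACC1|c1", "ACC2|c1", "ACC3|c1"), 1),
             bitscore = runif(1, 100, 300))))
  base <- classify_read(hits, tree, labels, classifier_params())
  for (i in 1:5) {
    perm <- hits[sample.int(nrow(hits)), ]
    expect_equal(classify_read(perm, tree, labels, classifier_params()), base)
  }

  reads_hits <- do.call(rbind, lapply(seq_len(80), function(i)
    make_hit(qseqid = paste0("r", i), pident = runif(1, 85, 100))))
  n_species <- vapply(seq(90, 98, by = 2), function(cut) {
    cls <- classify_reads(reads_hits, tree, labels,
                          classifier_params(species_min_identity = cut))
    sum(cls$assigned_rank == "species")
  }, numeric(1))
  expect_true(all(diff(n_species) <= 0))
})

test_that("profiles aggregate counts, roll up to genus and sum to 100", {
  tree <- fixture_label_tree()
  labels <- fixture_labels()
  hits <- rbind(
    do.call(rbind, lapply(1:80, function(i)
      make_hit(qseqid = paste0("a", i), pident = 99, sseqid = "ACC1|c1"))),
    do.call(rbind, lapply(1:20, function(i)
      make_hit(qseqid = paste0("b", i), pident = 99, sseqid = "ACC3|c1"))))
  cls <- classify_reads(hits, tree, labels)
  prof <- aggregate_profile(cls, tree)
  expect_equal(sort(prof$table$relative, decreasing = TRUE), c(80, 20))
  expect_equal(sum(prof$table$relative), 100, tolerance = 1e-9)
  g <- prof$rank_tables$genus
  expect_equal(sum(g$count), sum(prof$table$count))
  expect_equal(g$count[g$label == "Escherichia"], 80L)

  # all unclassified -> empty profile carrying the unclassified count
  cls0 <- classify_reads(make_hit(pident = 10), tree, labels,
                         read_ids = c("r1", "x", "y"))
  prof0 <- aggregate_profile(cls0, tree)
  expect_equal(nrow(prof0$table), 0L)
  expect_equal(prof0$unclassified_count, 3L)
})

test_that("genome-size normalization reweights counts by 1/size", {
  tree <- fixture_label_tree()
  labels <- fixture_labels()
  hits <- rbind(
    do.call(rbind, lapply(1:100, function(i)
      make_hit(qseqid = paste0("a", i), pident = 99, sseqid = "ACC1|c1"))),
    do.call(rbind, lapply(1:100, function(i)
      make_hit(qseqid = paste0("b", i), pident = 99, sseqid = "ACC3|c1"))))
  prof <- aggregate_profile(classify_reads(hits, tree, labels), tree)
  st <- c("Escherichia coli" = 2e6, "Lacticaseibacillus casei" = 4e6)
  norm <- normalize_by_genome_size(prof, st)
  tab <- norm$table
  expect_equal(tab$normalized[tab$label == "Escherichia coli"], 200 / 3,
               tolerance = 1e-9)
  expect_equal(tab$normalized[tab$label == "Lacticaseibacillus casei"],
               100 / 3, tolerance = 1e-9)
  expect_equal(sum(tab$normalized), 100, tolerance = 1e-9)
  # equal sizes leave the profile unchanged
  eq <- normalize_by_genome_size(prof, c("Escherichia coli" = 3e6,
                                         "Lacticaseibacillus casei" = 3e6))
  expect_equal(eq$table$normalized, prof$table$relative, tolerance = 1e-9)
  # single species -> 100%
  one <- aggregate_profile(classify_reads(
    make_hit(pident = 99), tree, labels), tree)
  expect_equal(normalize_by_genome_size(
    one, c("Escherichia coli" = 5e6))$table$normalized, 100)
  # missing species -> database-mean fallback with a warning
  expect_warning(normalize_by_genome_size(
    prof, c("Escherichia coli" = 2e6)), "missing from size table")
  expect_error(normalize_by_genome_size(prof, c("Escherichia coli" = 0)),
               "positive")
})
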