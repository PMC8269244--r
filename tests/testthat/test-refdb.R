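test_that("revise_taxonomy applies the ANI gate, coverage gate and genus retention", {
  gs <- fixture_genome_set()
  rev <- revise_taxonomy(gs, fixture_ani())
  lab <- function(acc) rev$labels$species[rev$labels$accession == acc]
  reason <- function(acc) rev$change_log$reason[rev$change_log$accession == acc]

  # ANI 96.2 with coverages 80/78 -> adopts the reference species
  expect_equal(lab("G1"), "Alpha primus")
  expect_equal(reason("G1"), "ani_reclassified")
  # ANI 96 but query coverage 60 fails the gate; closest reference genus
  # (Alpha) differs from the declared genus (Gamma) -> unresolved
  expect_equal(lab("G3"), "Gamma novus")
  expect_equal(reason("G3"), "unresolved")
  # ANI 90 below the gate, different genus -> unresolved, label kept
  expect_equal(lab("G4"), "Delta orphan")
  expect_equal(reason("G4"), "unresolved")
  # reference genomes keep their labels and are not logged
  expect_equal(lab("REF_A"), "Alpha primus")
  expect_false("REF_A" %in% rev$change_log$accession)
  expect_true(all(rev$change_log$reason %in%
                  c("ani_reclassified", "genus_retained", "unresolved")))
})

test_that("genus retention keeps the declared label when the closest reference only shares the genus", {
  gs <- fixture_genome_set()
  ani <- data.frame(query = "G3", subject = "REF_A", ani = 90,
                    query_cov = 80, subject_cov = 80)
  gs$meta$genus[gs$meta$accession == "G3"] <- "Alpha"  # now congeneric
  rev <- revise_taxonomy(gs, ani)
  expect_equal(rev$labels$species[rev$labels$accession == "G3"],
               "Gamma novus")
  expect_equal(rev$change_log$reason[rev$change_log$accession == "G3"],
               "genus_retained")
})

test_that("closest reference ties break on ANI, then min coverage, then accession", {
  gs <- fixture_genome_set()
  ani <- data.frame(
    query = c("G1", "G1"), subject = c("REF_B", "REF_A"),
    ani = c(96.2, 96.2), query_cov = c(90, 90), subject_cov = c(85, 80))
  rev <- revise_taxonomy(gs, ani)
  # REF_B wins on min coverage (85 vs 80)
  expect_equal(rev$labels$species[rev$labels$accession == "G1"],
               "Beta secundus")
  ani$subject_cov <- c(80, 80)
  rev2 <- revise_taxonomy(gs, ani)
  # full tie -> lexicographically smaller accession REF_A
  expect_equal(rev2$labels$species[rev2$labels$accession == "G1"],
               "Alpha primus")
  expect_error(revise_taxonomy(gs, data.frame(
    query = "NOPE", subject = "REF_A", ani = 95, query_cov = 80,
    subject_cov = 80)), "unknown accession")
})

test_that("dereplication drops only genomes above the ANI threshold to their species reference", {
  gs <- fixture_genome_set()
  rev <- revise_taxonomy(gs, fixture_ani())
  kept <- dereplicate(gs, rev$labels, fixture_ani())
  expect_false("G2" %in% kept)            # 99.5 > 99 to REF_A (its species ref)
  expect_true("G1" %in% kept)             # 96.2 <= 99
  expect_true(all(c("REF_A", "REF_B") %in% kept))  # references always retained
  expect_true("G4" %in% kept)             # no species reference -> retained
  # 98.9 stays below the threshold
  ani <- fixture_ani()
  ani$ani[ani$query == "G2"] <- 98.9
  expect_true("G2" %in% dereplicate(gs, rev$labels, ani))
})

test_that("raising the dereplication threshold never shrinks the retained set", {
  gs <- fixture_genome_set()
  rev <- revise_taxonomy(gs, fixture_ani())
  prev <- character(0)
  for (thr in c(94, 96, 98, 99, 99.9)) {
    kept <- dereplicate(gs, rev$labels, fixture_ani(),
                        curation_params(derep_threshold = thr))
    expect_true(all(prev %in% kept))
    prev <- kept
  }
})

test_that("contig length floors are kingdom-specific with strict-shorter removal", {
  mk <- function(n) random_dna(n)
  meta <- data.frame(
    accession = c("V", "P", "E"),
    species = c("v", "p", "e"), genus = c("v", "p", "e"),
    kingdom = c("viral", "prokaryotic", "eukaryotic"),
    is_reference = TRUE)
  contigs <- data.frame(
    accession = c("V", "V", "P", "P", "E", "E"),
    contig_id = c("a", "b", "a", "b", "a", "b"),
    sequence = c(mk(900), mk(1000), mk(4999), mk(5000), mk(11999), mk(11000)))
  gs <- filter_contigs_by_length(genome_set(meta, contigs))
  key <- paste(gs$contigs$accession, gs$contigs$contig_id)
  expect_setequal(key, c("V b", "P b"))      # 1000 and 5000 survive exactly
  expect_false("E" %in% gs$meta$accession)   # all-eukaryotic-short genome dropped
  expect_equal(gs$meta$total_length[gs$meta$accession == "P"], 5000)
})

test_that("host decontamination removes contigs on identity x coverage", {
  gs <- fixture_genome_set()
  hit_hi <- make_hit(qseqid = "REF_A|c1", pident = 95, qcovs = 80)
  hit_lo <- make_hit(qseqid = "REF_B|c1", pident = 95, qcovs = 10)
  out <- remove_host_contigs(gs, rbind(hit_hi, hit_lo))
  expect_false("REF_A" %in% out$meta$accession)  # 95% over 80% -> removed
  expect_true("REF_B" %in% out$meta$accession)   # coverage gate holds it
  expect_identical(remove_host_contigs(gs, NULL), gs)
  expect_error(remove_host_contigs(gs, make_hit(qseqid = "NOPE|c9")),
               "unknown contig")
})

test_that("size table is the per-species mean of retained genome lengths", {
  meta <- data.frame(accession = c("a", "b", "c"),
                     species = c("S one", "S one", "S two"),
                     genus = "G", kingdom = "prokaryotic",
                     is_reference = c(TRUE, FALSE, TRUE))
  contigs <- data.frame(
    accession = c("a", "b", "c"), contig_id = "c1",
    sequence = c(strrep("A", 6000), strrep("C", 8000), strrep("G", 5000)))
  gs <- genome_set(meta, contigs)
  labels <- meta[, c("accession", "genus", "species")]
  st <- build_size_table(gs, labels)
  expect_equal(st[["S one"]], 7000)
  expect_equal(st[["S two"]], 5000)
  expect_setequal(names(st), unique(labels$species))
})

test_that("full curation is idempotent and respects every floor", {
  gs <- fixture_genome_set()
  db1 <- curate_reference_db(gs, fixture_ani())
  db2 <- curate_reference_db(
    db1$genomes, fixture_ani()[fixture_ani()$query %in%
                                 db1$genomes$meta$accession, ])
  expect_setequal(db2$genomes$meta$accession, db1$genomes$meta$accession)
  expect_equal(sort(paste(db2$genomes$contigs$accession,
                          db2$genomes$contigs$contig_id)),
               sort(paste(db1$genomes$contigs$accession,
                          db1$genomes$contigs$contig_id)))
  floors <- db1$params$min_contig_length
  k <- db1$genomes$meta$kingdom[match(db1$genomes$contigs$accession,
                                      db1$genomes$meta$accession)]
  expect_true(all(nchar(db1$genomes$contigs$sequence) >= floors[k]))
  # change log covers exactly the non-reference genomes
  expect_setequal(db1$change_log$accession,
                  gs$meta$accession[!gs$meta$is_reference])
})

test_that("reference databases round-trip through their on-disk form", {
  db <- curate_reference_db(fixture_genome_set(), fixture_ani())
  d <- withr::local_tempdir()
  write_reference_db(db, d)
  db2 <- read_reference_db(d)
  expect_equal(db2$genomes$meta$accession, db$genomes$meta$accession)
  expect_equal(db2$genomes$contigs$sequence, db$genomes$contigs$sequence)
  expect_equal(db2$size_table[names(db$size_table)], db$size_table)
  expect_equal(db2$labels$species, db$labels$species)
  expect_equal(nrow(db2$change_log), nrow(db$change_log))
})
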