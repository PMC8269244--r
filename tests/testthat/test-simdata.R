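small_spec <- function(seed = 5, reads = c(60, 40)) {
  sim_spec(data.frame(name = c("Alpha one", "Beta two"),
                      length = c(20000, 30000), gc = c(0.4, 0.6),
                      reads = reads),
           seed = seed)
}

test_that("genome simulation honours length, GC content and the seed", {
  g <- simulate_genome(10000, gc = 0.5, seed = 3)
  expect_equal(nchar(g), 10000)
  expect_identical(simulate_genome(10000, gc = 0.5, seed = 3), g)
  big <- simulate_genome(100000, gc = 0.5, seed = 4)
  obs_gc <- sum(strsplit(big, "")[[1]] %in% c("G", "C")) / 100000
  sigma <- sqrt(0.5 * 0.5 / 100000)
  expect_lt(abs(obs_gc - 0.5), 3 * sigma)
  expect_error(simulate_genome(10000, gc = 1.2), "gc")
  expect_error(simulate_genome(500), ">= 1000")
})

test_that("illumina simulation emits exact per-species counts with a complete manifest", {
  sim <- simulate_illumina(small_spec())
  expect_equal(nrow(sim$reads), 100L)
  expect_equal(nrow(sim$manifest), 100L)
  cnt <- table(sim$manifest$species)
  expect_equal(cnt[["Alpha one"]], 60L)
  expect_equal(cnt[["Beta two"]], 40L)
  expect_setequal(sim$reads$read_id, sim$manifest$read_id)
  expect_equal(sum(sim$expected_profile), 100)
  expect_equal(sim$expected_profile[["Alpha one"]], 60)
  expect_true(all(nchar(sim$reads$sequence) == 150))
  expect_error(simulate_illumina(small_spec(reads = c(61, 40))), "even")
})

test_that("error-free illumina reads are exact genomic substrings at manifest coordinates", {
  spec <- small_spec()
  spec$base_error_rate <- 0
  sim <- simulate_illumina(spec)
  for (i in sample.int(nrow(sim$reads), 25)) {
    m <- sim$manifest[i, ]
    src <- substr(sim$genomes[[m$species]], m$start, m$end)
    if (m$strand == "-") src <- revcomp_chr(src)
    expect_identical(sim$reads$sequence[i], src)
  }
})

test_that("simulators are byte-identical across runs at a fixed seed", {
  s1 <- simulate_illumina(small_spec(seed = 11))
  s2 <- simulate_illumina(small_spec(seed = 11))
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$manifest, s2$manifest)
  n1 <- simulate_nanopore(small_spec(seed = 12))
  n2 <- simulate_nanopore(small_spec(seed = 12))
  expect_identical(n1$reads, n2$reads)
})

test_that("nanopore reads have the configured fixed length modulo indel drift", {
  spec <- small_spec(reads = c(6, 4))
  spec$long_read_length <- 8000
  sim <- simulate_nanopore(spec)
  expect_equal(nrow(sim$reads), 10L)
  expect_true(all(abs(nchar(sim$reads$sequence) - 8000) < 8000 * 0.01))
  spec0 <- spec
  spec0$long_read_error_rate <- 0
  sim0 <- simulate_nanopore(spec0)
  m <- sim0$manifest[1, ]
  src <- substr(sim0$genomes[[m$species]], m$start, m$end)
  if (m$strand == "-") src <- revcomp_chr(src)
  expect_identical(sim0$reads$sequence[1], src)
})

test_that("ANI fixtures validate accessions and can be symmetric", {
  rel <- data.frame(query = "g1", subject = "g2", ani = 99.5,
                    query_cov = 95, subject_cov = 90)
  tab <- make_ani_fixture(c("g1", "g2"), rel, symmetric = TRUE)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$query_cov[2], 90)   # coverages swap with the direction
  expect_error(make_ani_fixture(c("g1"), rel), "unknown accession")
})

test_that("planted ANI relations drive curation end to end", {
  set.seed(71)
  meta <- data.frame(
    accession = c("R1", "R2", "Q1", "Q2"),
    species = c("Ref one", "Ref two", "Ref one", "Declared other"),
    genus = c("GenA", "GenB", "GenA", "GenC"),
    kingdom = "prokaryotic",
    is_reference = c(TRUE, TRUE, FALSE, FALSE))
  contigs <- data.frame(accession = meta$accession, contig_id = "c1",
                        sequence = vapply(1:4, function(i) random_dna(6000),
                                          character(1)))
  gs <- genome_set(meta, contigs)
  # Q1 is a near-duplicate of its species reference; Q2 reclassifies to R2
  ani <- make_ani_fixture(meta$accession, data.frame(
    query = c("Q1", "Q2"), subject = c("R1", "R2"),
    ani = c(99.5, 96), query_cov = c(95, 80), subject_cov = c(95, 80)))
  db <- curate_reference_db(gs, ani)
  expect_false("Q1" %in% db$genomes$meta$accession)      # dereplicated
  expect_equal(db$labels$species[db$labels$accession == "Q2"], "Ref two")
  # with no relations, everything is retained and flagged unresolved
  db0 <- curate_reference_db(gs, make_ani_fixture(meta$accession,
    data.frame(query = character(0), subject = character(0),
               ani = numeric(0), query_cov = numeric(0),
               subject_cov = numeric(0))))
  expect_setequal(db0$genomes$meta$accession, meta$accession)
  expect_true(all(db0$change_log$reason == "unresolved"))
})

test_that("simulated read sets round-trip through FASTQ with sidecar files", {
  sim <- simulate_illumina(small_spec(seed = 9))
  d <- withr::local_tempdir()
  paths <- write_sim_output(sim, d)
  r1 <- read_fastq(file.path(d, "sim_R1.fastq"))
  r2 <- read_fastq(file.path(d, "sim_R2.fastq"))
  expect_equal(nrow(r1) + nrow(r2), nrow(sim$reads))
  expect_setequal(c(r1$read_id, r2$read_id), sim$reads$read_id)
  expect_equal(r1$sequence[1],
               sim$reads$sequence[sim$reads$read_id == r1$read_id[1]])
  man <- read.delim(file.path(d, "sim_manifest.tsv"))
  expect_equal(nrow(man), nrow(sim$manifest))
  prof <- read.delim(file.path(d, "sim_expected_profile.tsv"))
  expect_equal(sum(prof$expected_relative), 100)
})
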