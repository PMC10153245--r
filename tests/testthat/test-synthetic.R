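test_that("backbone sequences hit the target GC and are deterministic", {
  g <- generate_backbone(100000, 0.5, seed = 1)
  seq <- as.character(g$contigs[[1]])
  expect_equal(nchar(seq), 100000)
  gc <- sum(strsplit(seq, "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.5), 0.02)
  g2 <- generate_backbone(5000, 0.5, seed = 1)
  g3 <- generate_backbone(5000, 0.5, seed = 1)
  expect_identical(as.character(g2$contigs), as.character(g3$contigs))
  expect_error(generate_backbone(0, 0.5, 1), "at least")
  expect_error(generate_backbone(10000, 1.2, 1), "inside")
  # host genes exist, alternate strand in blocks, and lie in bounds
  expect_gt(nrow(g$cds), 50)
  expect_true(all(g$cds$end <= 100000))
  expect_true(all(c("+", "-") %in% g$cds$strand))
})

test_that("prophage cassettes carry att repeats, strand runs and marker enrichment", {
  set.seed(5)
  markers <- random_marker_kmers(50, 12)
  cass <- generate_prophage(20000, markers, seed = 7)
  expect_equal(nchar(cass$seq), 20000)
  expect_identical(substr(cass$seq, 1, 12), substr(cass$seq, 19989, 20000))
  run_frac <- max(table(cass$cds$strand)) / nrow(cass$cds)
  expect_gte(run_frac, 0.8)
  # marker-score enrichment over a plain backbone of the same length
  score_cass <- kmer_phage_score(cass$seq, markers, 12)
  backbone <- as.character(generate_backbone(20000, 0.5, seed = 8)$contigs[[1]])
  score_back <- kmer_phage_score(backbone, markers, 12)
  expect_gte(score_cass, 5 * max(score_back, 50 / 4^12 * 12))
  expect_error(generate_prophage(1000, markers, min_gene_len = 300),
               "cannot host 5 genes")
})

test_that("planting hits the target density band and records exact truth", {
  spec <- synthetic_spec(n_genomes = 1, seed = 3)
  g <- generate_backbone(2.3e6, 0.5, seed = 3, accession = "ACC_1.1")
  pl <- plant_prophages(g, spec, seed = 9)
  total <- sum(pl$truth$length)
  # 0.024 x 2.3 Mbp = 55,200 host-relative bp, +/- 20%
  expect_gte(total, 44160)
  expect_lte(total, 66240)
  # truth coordinates match the inserted cassettes (non-overlap, in bounds,
  # away from edges)
  tr <- dplyr::arrange(pl$truth, start)
  expect_true(all(diff(tr$start) > 0))
  expect_true(all(tr$start > 2500))
  expect_true(all(tr$end < genome_length(pl$genome) - 2500))
  expect_true(all(tr$end - tr$start + 1 == tr$length))
  # genome grew by exactly the planted bp
  expect_equal(genome_length(pl$genome), 2.3e6 + total)
  # att pair present at the recorded coordinates
  seq <- as.character(pl$genome$contigs[[tr$contig_id[1]]])
  expect_identical(substr(seq, tr$start[1], tr$start[1] + 11),
                   substr(seq, tr$end[1] - 11, tr$end[1]))
})

test_that("planting is deterministic and a zero target leaves the genome alone", {
  spec <- synthetic_spec(n_genomes = 1, seed = 3)
  g <- generate_backbone(5e5, 0.5, seed = 4)
  a <- plant_prophages(g, spec, seed = 11)
  b <- plant_prophages(g, spec, seed = 11)
  expect_identical(a$truth, b$truth)
  expect_identical(as.character(a$genome$contigs), as.character(b$genome$contigs))
  spec0 <- synthetic_spec(n_genomes = 1, target_density = 0, seed = 3)
  z <- plant_prophages(g, spec0, seed = 11)
  expect_identical(as.character(z$genome$contigs), as.character(g$contigs))
  expect_equal(nrow(z$truth), 0)
})

test_that("cohorts honour the lysogen fraction and are reproducible", {
  spec <- synthetic_spec(n_genomes = 200, lysogen_fraction = 0.94, seed = 17)
  co <- generate_cohort(spec, sequences = FALSE)
  nl <- sum(co$genome_meta$is_lysogen)
  expect_gte(nl, 182)
  expect_lte(nl, 194)
  expect_equal(nrow(co$metadata), 200)
  co2 <- generate_cohort(spec, sequences = FALSE)
  expect_identical(co$metadata, co2$metadata)
  expect_identical(co$truth, co2$truth)
  one <- generate_cohort(synthetic_spec(n_genomes = 1, seed = 1),
                         sequences = FALSE)
  expect_length(one$genomes, 1)
  expect_equal(nrow(one$metadata), 1)
})

test_that("cohort mean density converges to the target", {
  spec <- synthetic_spec(n_genomes = 200, genome_len_range = c(2e6, 6e6),
                         lysogen_fraction = 1, seed = 23)
  co <- generate_cohort(spec, sequences = FALSE)
  m <- mean(co$genome_meta$true_density)
  expect_lt(abs(m - 0.024), 0.1 * 0.024)
})

test_that("planted regions round-trip byte-identically through GenBank files", {
  co <- generate_cohort(synthetic_spec(n_genomes = 2, genome_len_mode = 4e5,
                                       genome_len_spread = 5e4, seed = 12))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  for (g in co$genomes) {
    rt <- read_genbank(file.path(dir, paste0(g$accession, ".gbff")))
    tr <- co$truth[co$truth$accession == g$accession, ]
    for (i in seq_len(nrow(tr))) {
      orig <- substr(as.character(g$contigs[[tr$contig_id[i]]]),
                     tr$start[i], tr$end[i])
      back <- substr(as.character(rt$contigs[[tr$contig_id[i]]]),
                     tr$start[i], tr$end[i])
      expect_identical(back, orig)
    }
  }
  md <- read.delim(file.path(dir, "metadata.tsv"))
  expect_equal(nrow(md), 2)
})

test_that("MAG degradation removes prophages at the stated rate", {
  # loss 0 keeps everything, loss 1 removes everything
  co <- generate_cohort(synthetic_spec(n_genomes = 1, genome_len_mode = 5e5,
                                       genome_len_spread = 1e4, seed = 6))
  g <- co$genomes[[1]]
  tr <- co$truth
  keep <- mag_degrade(g, tr, loss_prob = 0, seed = 1)
  expect_identical(as.character(keep$genome$contigs), as.character(g$contigs))
  gone <- mag_degrade(g, tr, loss_prob = 1, seed = 1)
  expect_equal(sum(gone$truth$retained), 0)
  # every excision splits a contig
  expect_equal(nrow(gone$genome$contig_lengths),
               1 + sum(tr$retained))
  # removed bp are really gone
  expect_equal(genome_length(gone$genome),
               genome_length(g) - sum(tr$length))
  # binomial retention band: 300 planted, loss 2/3 -> retained in [80, 120]
  big <- generate_cohort(synthetic_spec(n_genomes = 45, lysogen_fraction = 1,
                                        genome_len_range = c(5e6, 9e6),
                                        seed = 44), sequences = FALSE)
  n_planted <- sum(big$truth$retained)
  expect_gte(n_planted, 250)  # enough planted prophages for the band check
  set.seed(91)
  kept_n <- 0
  for (acc in unique(big$truth$accession)) {
    gi <- which(vapply(big$genomes, function(x) x$accession, "") == acc)
    md <- mag_degrade(big$genomes[[gi]], big$truth[big$truth$accession == acc, ],
                      loss_prob = 2 / 3)
    kept_n <- kept_n + sum(md$truth$retained)
  }
  expect_gte(kept_n / n_planted, 80 / 300)
  expect_lte(kept_n / n_planted, 120 / 300)
})

test_that("length mixtures are honoured per component", {
  cmp <- data.frame(weight = c(0.5, 0.5), mode = c(15000, 45000),
                    sd = c(3000, 5000))
  spec <- synthetic_spec(n_genomes = 40, prophage_len_components = cmp,
                         lysogen_fraction = 1,
                         genome_len_range = c(3e6, 6e6), seed = 13)
  co <- generate_cohort(spec, sequences = FALSE)
  lens <- co$truth$length
  expect_gt(length(lens), 50)
  m1 <- median(lens[co$truth$component == 1])
  m2 <- median(lens[co$truth$component == 2])
  expect_lt(m1, m2)
  expect_error(synthetic_spec(prophage_len_components =
                                data.frame(weight = c(0.4, 0.4),
                                           mode = c(1e4, 2e4),
                                           sd = c(1e3, 1e3))),
               "sum to 1")
})

test_that("spec invariants are enforced", {
  expect_error(synthetic_spec(target_density = 1.2), "fraction")
  expect_error(synthetic_spec(lysogen_fraction = -0.1), "fraction")
  expect_error(synthetic_spec(backbone_gc = 0), "inside")
  expect_error(synthetic_spec(prophage_len_mode = 1000), "min_cassette_len")
})
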