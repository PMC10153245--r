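# brute-force six-frame ORF oracle: enumerate every in-frame ATG, extend to
# the first in-frame stop, keep the leftmost ATG per stop
orf_oracle <- function(seq, min_len = 90) {
  seq <- toupper(seq)
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  scan <- function(s) {
    m <- nchar(s)
    hits <- list()
    for (a in seq_len(max(0, m - 2))) {
      if (substr(s, a, a + 2) != "ATG") next
      p <- a
      repeat {
        if (p + 2 > m) { p <- NA; break }
        if (substr(s, p, p + 2) %in% c("TAA", "TAG", "TGA")) break
        p <- p + 3
      }
      if (is.na(p)) next
      hits[[length(hits) + 1L]] <- c(a, p + 2)
    }
    if (!length(hits)) return(NULL)
    h <- unique(do.call(rbind, hits))
    # leftmost ATG per (frame, stop)
    keep <- !duplicated(h[, 2])
    h <- h[keep, , drop = FALSE]
    h[h[, 2] - h[, 1] + 1 >= min_len, , drop = FALSE]
  }
  fwd <- scan(seq)
  rev_ <- scan(revcomp(seq))
  m <- nchar(seq)
  out <- list()
  if (!is.null(fwd) && nrow(fwd))
    out$f <- tibble::tibble(start = fwd[, 1], end = fwd[, 2], strand = "+")
  if (!is.null(rev_) && nrow(rev_))
    out$r <- tibble::tibble(start = m - rev_[, 2] + 1,
                            end = m - rev_[, 1] + 1, strand = "-")
  dplyr::arrange(dplyr::bind_rows(out), start, end)
}

test_that("ORF calling finds constructed and brute-force-verified ORFs", {
  # a single clean forward ORF: ATG + 97 sense codons + TAA = 300 bp
  body <- strrep("GCT", 98)
  orf <- paste0("ATG", body, "TAA")
  pad <- strrep("C", 50)
  seq <- paste0(pad, orf, pad)
  got <- call_orfs(seq, min_orf_len = 90)
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 51)
  expect_equal(got$end, 50 + nchar(orf))
  expect_equal(got$strand, "+")

  expect_equal(nrow(call_orfs(strrep("N", 500))), 0)

  set.seed(21)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
    got <- call_orfs(s, min_orf_len = 90)
    want <- orf_oracle(s, min_len = 90)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$strand, want$strand)
  }
})

test_that("skew deviations follow the (G-C)/(G+C) and (A-T)/(A+T) definitions", {
  orfs <- tibble::tibble(start = c(1, 5, 9), end = c(4, 8, 12))
  seq <- paste0("GGGG", "GCGC", "TTTT")
  sk <- compute_skews(seq, orfs, c(gc_skew = 0, at_skew = 0))
  expect_equal(sk$gc_skew_dev, c(1, 0, 0))
  expect_equal(sk$at_skew_dev[3], -1)
  sk2 <- compute_skews(seq, orfs[3, ], c(gc_skew = 0, at_skew = 0.2))
  expect_equal(sk2$at_skew_dev, -1.2)
})

test_that("marker k-mer scores count window membership exactly", {
  markers <- c("ACGTACGTACGT", "GGGGGGGGGGGG")
  expect_equal(kmer_phage_score(strrep("CA", 30), markers), 0)
  expect_equal(kmer_phage_score(strrep("G", 40), markers), 1)
  # a 20-mer whose 9 windows contain exactly 2 marker positions, counted by
  # hand: ACGTACGTACGT at offsets 1 and 5
  s <- paste0("ACGTACGTACGTACGT", "TTTT")
  hand <- mean(vapply(1:9, function(i)
    substr(s, i, i + 11) %in% markers, logical(1)))
  expect_equal(kmer_phage_score(s, markers), hand)
  expect_equal(hand, 2 / 9)
  expect_warning(sc <- kmer_phage_score("ACGT", markers), "shorter")
  expect_equal(sc, 0)
})

test_that("window metrics aggregate median length, runs and means", {
  orfs <- tibble::tibble(
    contig_id = "c", start = seq(1, by = 1000, length.out = 3),
    end = seq(1, by = 1000, length.out = 3) + c(299, 599, 899),
    strand = c("+", "+", "+"), length = c(300, 600, 900),
    phage_kmer_score = c(0, 0.5, 1), gc_skew_dev = c(0, 0, 0.3),
    at_skew_dev = c(0, 0, 0))
  m <- window_metrics(orfs, window_size = 3)
  expect_equal(m$median_orf_len[2], 600)
  expect_equal(m$same_strand_run, rep(1, 3))
  expect_equal(m$phage_kmer_score[2], 0.5)

  n <- 30
  alt <- tibble::tibble(
    contig_id = "c", start = seq(1, by = 500, length.out = n),
    end = seq(1, by = 500, length.out = n) + 299,
    strand = rep(c("+", "-"), n / 2), length = rep(300, n),
    phage_kmer_score = 0, gc_skew_dev = 0, at_skew_dev = 0)
  ma <- window_metrics(alt, window_size = 30)
  expect_equal(ma$same_strand_run[15], 1 / 30)   # longest run 1 of 30
  same <- alt
  same$strand <- "+"
  ms <- window_metrics(same, window_size = 30)
  expect_equal(ms$same_strand_run[15], 1)
})

test_that("the classifier separates simulator classes and rejects bad input", {
  td <- fixture_training_data()
  model <- fixture_model()
  expect_gte(model$oob_accuracy, 0.95)
  # held-out split confirms the OOB signal
  set.seed(33)
  ix <- sample(nrow(td$metrics), 500)
  pred <- predict(model, td$metrics[ix, ], type = "class")
  expect_gte(mean(pred == td$labels[ix]), 0.95)

  # shuffled labels on a class-balanced subset carry no signal
  set.seed(34)
  ph <- which(td$labels == "phage")
  ho <- sample(which(td$labels == "host"), length(ph))
  sub <- c(ph, ho)
  shuf <- train_classifier(td$metrics[sub, ], sample(td$labels[sub]),
                           n_trees = 100, seed = 1)
  expect_lt(abs(shuf$oob_accuracy - 0.5), 0.1)

  # determinism under seed
  m1 <- train_classifier(td$metrics[sub, ], td$labels[sub], n_trees = 50,
                         seed = 5)
  m2 <- train_classifier(td$metrics[sub, ], td$labels[sub], n_trees = 50,
                         seed = 5)
  expect_identical(predict(m1, td$metrics[1:50, ]),
                   predict(m2, td$metrics[1:50, ]))

  expect_error(train_classifier(td$metrics[1:50, ], td$labels[1:50]),
               "at least 100")
  one_class <- which(td$labels == "host")[1:200]
  expect_error(train_classifier(td$metrics[one_class, ],
                                td$labels[one_class]), "both classes")
  expect_error(predict(model, td$metrics[1:5, 1:2]), "schema")
})

test_that("region assembly applies the minimum-gene and gap rules", {
  mk <- function(phage) tibble::tibble(
    contig_id = "c", start = seq(1, by = 1000, length.out = length(phage)),
    end = seq(1, by = 1000, length.out = length(phage)) + 500,
    phage = phage)
  r6 <- assemble_regions(mk(rep(TRUE, 6)))
  expect_equal(nrow(r6), 1)
  expect_equal(r6$n_genes, 6)
  expect_equal(r6$status, "pending")

  r4 <- assemble_regions(mk(c(FALSE, rep(TRUE, 4), FALSE)))
  expect_equal(r4$status, "discarded")
  expect_equal(r4$discard_reason, "too_few_genes")

  pat <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  with_gap <- assemble_regions(mk(pat), gap_tolerance = 1)
  expect_equal(nrow(with_gap), 1)
  expect_equal(with_gap$n_genes, 5)
  expect_equal(with_gap$status, "pending")
  no_gap <- assemble_regions(mk(pat), gap_tolerance = 0)
  expect_equal(nrow(no_gap), 2)
  expect_equal(no_gap$n_genes, c(3, 2))
  expect_true(all(no_gap$status == "discarded"))
})

test_that("boundary refinement snaps to the longest repeat with stated tie-breaks", {
  set.seed(55)
  base <- paste(sample(c("A", "C", "G", "T"), 12000, replace = TRUE),
                collapse = "")
  # a 20 bp att pair: long enough that no chance repeat in the 4 kb flanks
  # can compete (expected count ~ 4000^2 / 4^20 << 1)
  att <- "ACGTTGCAAGTCGTTACCAG"
  seq <- base
  substr(seq, 3001, 3020) <- att
  substr(seq, 8981, 9000) <- att
  # prevent chance extension at the four adjacent bases
  substr(seq, 3000, 3000) <- "A"; substr(seq, 8980, 8980) <- "C"
  substr(seq, 3021, 3021) <- "G"; substr(seq, 9001, 9001) <- "T"
  region <- tibble::tibble(contig_id = "c", start = 3400L, end = 8600L,
                           n_genes = 10L, status = "pending",
                           discard_reason = NA_character_)
  ref <- refine_boundaries(region, seq, extra_dna = 2000, min_repeat_len = 12)
  expect_equal(ref$start, 3001L)
  expect_equal(ref$end, 9000L)
  expect_equal(ref$att_len, 20L)

  # no qualifying repeat (none of length >= 25 by chance): unchanged
  left_alone <- refine_boundaries(region, base,
                                  extra_dna = 2000, min_repeat_len = 25)
  expect_equal(left_alone$start, 3400L)
  expect_true(is.na(left_alone$att_len))

  # a longer pair beats a shorter one regardless of displacement
  seq2 <- base
  short_r <- "GATCCGATAGGCTTAC"       # 16 bp, close to the boundaries
  long_r <- "TTGACCGTAAGGCTAAGCCT"    # 20 bp, far from the boundaries
  substr(seq2, 3390, 3405) <- short_r; substr(seq2, 8610, 8625) <- short_r
  substr(seq2, 1600, 1619) <- long_r;  substr(seq2, 10200, 10219) <- long_r
  ref2 <- refine_boundaries(region, seq2, extra_dna = 2000,
                            min_repeat_len = 16)
  expect_gte(ref2$att_len, 20L)
  expect_lte(abs(ref2$att_left - 1600L), 2L)  # chance extension tolerated

  # equal lengths: the pair minimising total boundary displacement wins
  seq3 <- base
  near <- "CCGTATTAGGCCAATTGGCA"
  far <- "GGATCCTTAAGCGCGTTAAC"
  substr(seq3, 3390, 3409) <- near; substr(seq3, 8610, 8629) <- near
  substr(seq3, 1600, 1619) <- far;  substr(seq3, 10200, 10219) <- far
  # block extension: bases adjacent to the two copies of each pair differ
  substr(seq3, 3389, 3389) <- "A"; substr(seq3, 8609, 8609) <- "C"
  substr(seq3, 3410, 3410) <- "G"; substr(seq3, 8630, 8630) <- "T"
  substr(seq3, 1599, 1599) <- "A"; substr(seq3, 10199, 10199) <- "C"
  substr(seq3, 1620, 1620) <- "G"; substr(seq3, 10220, 10220) <- "T"
  ref3 <- refine_boundaries(region, seq3, extra_dna = 2000,
                            min_repeat_len = 20)
  expect_equal(ref3$att_len, 20L)
  expect_equal(ref3$att_left, 3390L)   # smaller total displacement
})

test_that("verification requires annotation or database evidence", {
  orfs <- tibble::tibble(
    start = seq(1000, by = 2000, length.out = 6),
    end = seq(1000, by = 2000, length.out = 6) + 999,
    annotation = c("phage major capsid protein", rep("hypothetical protein", 5)),
    hit = rep(FALSE, 6))
  region <- tibble::tibble(contig_id = "c", start = 500L, end = 12000L,
                           n_genes = 6L, status = "pending",
                           discard_reason = NA_character_)
  kept <- verify_region(region, orfs)
  expect_equal(kept$status, "kept")
  expect_equal(kept$phage_annotated_genes, 1)

  orfs2 <- orfs
  orfs2$annotation <- "hypothetical protein"
  disc <- verify_region(region, orfs2)
  expect_equal(disc$status, "discarded")
  expect_equal(disc$discard_reason, "no_phage_evidence")

  # verified fraction is the hit-ORF bp share of the region
  orfs3 <- orfs2
  orfs3$hit <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  region3 <- tibble::tibble(contig_id = "c", start = 1000L, end = 4999L,
                            n_genes = 6L, status = "pending",
                            discard_reason = NA_character_)
  v <- verify_region(region3, orfs3)
  expect_equal(v$verified_bp_fraction, 0.5)
  expect_equal(v$status, "kept")   # provider hits count as evidence
})

test_that("detection recovers planted prophages and reports discards", {
  co <- fixture_cohort()
  regs <- fixture_detect()
  rec <- region_recovery(regs, co$truth)
  expect_gte(rec$sensitivity, 0.8)
  expect_gte(rec$precision, 0.8)
  expect_true(all(regs$status %in% c("kept", "discarded")))
  # kept regions are disjoint within each contig
  kept <- regs[regs$status == "kept", ]
  for (k in split(kept, paste(kept$accession, kept$contig_id))) {
    k <- dplyr::arrange(k, start)
    if (nrow(k) > 1) expect_true(all(k$start[-1] > k$end[-nrow(k)]))
  }
  expect_true(all(kept$n_genes >= 5))
})

test_that("detection is deterministic and invariant to contig order", {
  co <- fixture_cohort()
  model <- fixture_model()
  cfg <- run_config()
  g <- co$genomes[[1]]
  r1 <- detect(g, model, co$marker_set, cfg)
  r2 <- detect(g, model, co$marker_set, cfg)
  expect_identical(r1, r2)

  # two-contig genome scanned in either order gives the same regions
  g2 <- genome_record("TWO_1.1",
                      contigs = c(x = as.character(co$genomes[[1]]$contigs[[1]]),
                                  y = as.character(co$genomes[[2]]$contigs[[1]])),
                      cds = dplyr::bind_rows(
                        dplyr::mutate(co$genomes[[1]]$cds, contig_id = "x"),
                        dplyr::mutate(co$genomes[[2]]$cds, contig_id = "y")))
  g2r <- genome_record("TWO_1.1",
                       contigs = c(y = as.character(co$genomes[[2]]$contigs[[1]]),
                                   x = as.character(co$genomes[[1]]$contigs[[1]])),
                       cds = dplyr::bind_rows(
                         dplyr::mutate(co$genomes[[2]]$cds, contig_id = "y"),
                         dplyr::mutate(co$genomes[[1]]$cds, contig_id = "x")))
  ra <- dplyr::arrange(detect(g2, model, co$marker_set, cfg), contig_id, start)
  rb <- dplyr::arrange(detect(g2r, model, co$marker_set, cfg), contig_id, start)
  attr(ra, "n_orfs") <- NULL; attr(rb, "n_orfs") <- NULL
  expect_equal(ra, rb)
})

test_that("raising the decision threshold never increases kept prophage bp", {
  co <- fixture_cohort()
  model <- fixture_model()
  cfg <- run_config()
  g <- co$genomes[[1]]
  bp_at <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th) {
    m <- model
    m$threshold <- th
    r <- detect(g, m, co$marker_set, cfg)
    k <- r[r$status == "kept", ]
    sum(k$end - k$start + 1)
  }, numeric(1))
  expect_true(all(diff(bp_at) <= 0))
})

test_that("short-contig genomes yield an empty, logged result", {
  g <- genome_record("S_1.1", contigs = c(tiny = strrep("ACGT", 500)))
  expect_message(r <- detect(g, fixture_model(), fixture_cohort()$marker_set,
                             run_config()),
                 "no contig reaches")
  expect_equal(nrow(r), 0)
})

test_that("GFF3 export round-trips region coordinates", {
  regs <- fixture_detect()
  one <- regs[regs$accession == regs$accession[1], ]
  f <- withr::local_tempfile(fileext = ".gff3")
  export_regions_gff3(one, f)
  back <- rtracklayer::import(f)
  expect_equal(length(back), nrow(one))
  expect_equal(GenomicRanges::start(back), one$start)
  expect_equal(GenomicRanges::end(back), one$end)
  expect_identical(as.character(back$status), one$status)
})

test_that("the HMM provider validates its inputs", {
  expect_error(hit_provider_hmmer("/no/such/file.hmm"), "not found")
})
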