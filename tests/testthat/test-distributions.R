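test_that("prophage density follows its definition and is scale-free", {
  expect_equal(prophage_density(24000, 1e6), 0.024)
  expect_equal(prophage_density(0, 2e6), 0)
  expect_equal(prophage_density(1e5, 1e6), 0.1)
  set.seed(1)
  for (rep in 1:20) {
    p <- runif(1, 0, 1e5); h <- runif(1, 1e5, 1e7); k <- runif(1, 0.1, 50)
    expect_equal(prophage_density(k * p, k * h), prophage_density(p, h))
  }
  expect_error(prophage_density(100, 0), "positive")
  expect_error(prophage_density(-1, 100), "non-negative")
})

test_that("genome summaries link detector output, lengths and metadata", {
  co <- fixture_cohort()
  regs <- fixture_detect()
  s <- genome_summaries(regs, co$genomes, metadata = co$metadata)
  expect_equal(nrow(s), length(co$genomes))
  expect_true(all(s$density == s$prophage_bp / s$genome_bp))
  expect_identical(s$is_lysogen, s$n_prophages >= 1)
  expect_true("phylum" %in% names(s))
  expect_true("isolation_year" %in% names(s))
  # detector-based densities agree with planted truth to within the
  # boundary fuzz of the detector
  ts <- truth_summaries(co)
  j <- dplyr::inner_join(s, ts, by = "accession", suffix = c("_det", "_true"))
  lys <- j[j$is_lysogen_true, ]
  expect_true(all(abs(lys$density_det - lys$density_true) <
                    0.5 * lys$density_true + 0.002))
})

test_that("genome-size binning is left-closed right-open and excludes overflow", {
  s <- tibble::tibble(genome_bp = c(1.4e6, 1.4e6 - 1, 5e6, 1.3e7),
                      density = c(0.02, 0.02, 0.03, 0.04),
                      concentration = 1, concentration_per_mbp = 1,
                      is_lysogen = TRUE, n_prophages = 1)
  expect_message(b <- bin_by_genome_size(s), "excluded")
  expect_equal(sort(b$bin), c(0, 1, 3))     # 1.4e6 - 1 in bin 0, 1.4e6 in bin 1
  expect_equal(sum(b$n), 3)                 # the 1.3e7 genome dropped
  # identical genomes give the common density in their bin
  s2 <- s[rep(3, 10), ]
  b2 <- suppressMessages(bin_by_genome_size(s2))
  expect_equal(b2$mean_density, 0.03)
  # non-lysogens excluded by default, included on request
  s3 <- s[1:3, ]
  s3$is_lysogen[1] <- FALSE
  expect_equal(sum(suppressMessages(bin_by_genome_size(s3))$n), 2)
  expect_equal(sum(suppressMessages(
    bin_by_genome_size(s3, lysogens_only = FALSE))$n), 3)
  expect_error(bin_spec(step = 0), "positive")
  expect_error(bin_spec(minimum = 5, maximum = 5), "exceed")
})

test_that("constant planted density is flat across genome-size bins", {
  co <- generate_cohort(synthetic_spec(n_genomes = 200, lysogen_fraction = 1,
                                       genome_len_range = c(2e6, 1e7),
                                       seed = 77), sequences = FALSE)
  s <- truth_summaries(co)
  b <- suppressMessages(bin_by_genome_size(s))
  b <- b[b$bin_lo >= 2e6 & b$n >= 5, ]
  expect_gte(nrow(b), 4)
  overall <- stats::weighted.mean(b$mean_density, b$n)
  expect_true(all(abs(b$mean_density - overall) <= 0.1 * overall))
})

test_that("the KDE recovers the planted length mode and normalises", {
  co <- generate_cohort(synthetic_spec(n_genomes = 400, lysogen_fraction = 1,
                                       genome_len_range = c(3e6, 6e6),
                                       seed = 31), sequences = FALSE)
  lens <- co$truth$length
  expect_gt(length(lens), 1500)
  k <- kde(lens)
  expect_lt(abs(attr(k, "mode") - 20000), 0.1 * 20000)
  expect_lt(abs(attr(k, "integral") - 1), 1e-3)
  # symmetric sample: argmax within one grid step of the median
  set.seed(4)
  sym <- rnorm(5000)
  ks <- kde(sym)
  step <- diff(ks$x[1:2])
  expect_lt(abs(attr(ks, "mode") - median(sym)), 3 * step + attr(ks, "bw"))
  expect_error(kde(rep(1, 10)), "histogram")
  expect_error(kde(1), "at least 2")
})

test_that("trend regression reproduces hand-computed fits", {
  x <- 1:10
  # lm warns that a perfect fit makes the F statistic unreliable; the
  # coefficients are what is under test
  ex <- suppressWarnings(trend_regression(x, 2 * x + 1))
  expect_equal(ex$slope, 2)
  expect_equal(ex$intercept, 1)
  expect_equal(ex$r_squared, 1)

  tb <- trend_regression(c(1, 2, 3), c(2, 4, 5))
  expect_equal(tb$slope, 1.5)

  set.seed(10)
  null <- trend_regression(rnorm(1000), rnorm(1000))
  expect_lt(abs(null$slope), 0.12)
  expect_gt(null$p_value, 1e-4)

  expect_error(trend_regression(rep(1, 5), 1:5), "constant")
  expect_error(trend_regression(1:2, 1:2), "at least 3")
})

test_that("MAG-isolate comparison reports group statistics and a rank test", {
  s <- tibble::tibble(density = c(rep(0.03, 10), rep(0.03, 10)),
                      is_mag = rep(c(FALSE, TRUE), each = 10))
  same <- mag_isolate_comparison(s)
  expect_equal(same$mag_to_isolate_ratio, 1)
  expect_gte(same$p_value, 0.9)

  tiny <- tibble::tibble(density = c(0.01, 0.03), is_mag = c(TRUE, FALSE))
  expect_equal(mag_isolate_comparison(tiny)$p_value, 1)

  expect_error(mag_isolate_comparison(
    tibble::tibble(density = 0.1, is_mag = TRUE)), "non-empty")
  g <- glance(mag_isolate_comparison(s))
  expect_named(g, c("mag_to_isolate_ratio", "p.value"))
})

test_that("prophage count and total length are tightly related on the cohort", {
  # a narrow cassette-length distribution gives a near-deterministic
  # count-to-bp relation
  co <- generate_cohort(synthetic_spec(n_genomes = 300, lysogen_fraction = 1,
                                       prophage_len_sd = 3000,
                                       genome_len_range = c(2e6, 9e6),
                                       seed = 55), sequences = FALSE)
  s <- truth_summaries(co)
  fit <- trend_regression(s$n_prophages, s$prophage_bp)
  expect_gte(fit$r_squared, 0.9)
})

test_that("verified-fraction aggregation and regressions behave at the extremes", {
  regs <- tibble::tibble(
    phylum = rep(c("P1", "P2", "P3", "P4"), each = 5),
    start = 1, end = 20000,
    verified_bp_fraction = 1, status = "kept")
  va <- verified_fraction_analysis(regs)
  expect_true(all(va$per_phylum$fraction == 1))
  regs$verified_bp_fraction <- 0
  expect_true(all(verified_fraction_analysis(regs)$per_phylum$fraction == 0))

  # hit rate independent of proposed bp: slope not significant
  set.seed(9)
  regs2 <- tibble::tibble(
    phylum = rep(paste0("P", 1:12), times = sample(3:30, 12, replace = TRUE)))
  regs2$start <- 1
  regs2$end <- round(runif(nrow(regs2), 8000, 40000))
  regs2$verified_bp_fraction <- pmin(1, pmax(0, rnorm(nrow(regs2), 0.5, 0.1)))
  regs2$status <- "kept"
  va2 <- verified_fraction_analysis(
    regs2, phylum_first_described = tibble::tibble(
      phylum = paste0("P", 1:12), year = 1900 + seq(0, 110, by = 10)))
  expect_gt(va2$vs_proposed_bp$p_value, 0.05)
  expect_true(!is.null(va2$vs_year))
})

test_that("dip test p-values are close to uniform under a unimodal null", {
  set.seed(19)
  nd <- dip_null_distribution(n = 80, n_boot = 500, seed = 3)
  ps <- vapply(1:120, function(i)
    dip_test(runif(80), null_dips = nd)$p_value, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
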