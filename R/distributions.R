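#' Genomic prophage density
#'
#' The ratio of total prophage DNA to host genome length excluding the
#' prophage regions: 24 bp of prophage per 1,000 bp of host DNA is a
#' density of 0.024. Scale-free and vectorised.
#'
#' @param prophage_bp Total prophage bp per genome (>= 0).
#' @param host_bp Host genome bp excluding prophages (> 0).
#' @return `prophage_bp / host_bp`.
#' @export
prophage_density <- function(prophage_bp, host_bp) {
  if (any(host_bp <= 0)) stop("host_bp must be strictly positive")
  if (any(prophage_bp < 0)) stop("prophage_bp must be non-negative")
  prophage_bp / host_bp
}

#' Roll detector output up into per-genome summaries
#'
#' One row per genome: host bp (detection universe minus kept prophage
#' bp), prophage bp, counts, density, concentration, lysogen flag, and --
#' when metadata are supplied -- isolation year, country, MAG flag and
#' taxonomy ranks.
#'
#' @param regions Detector output across genomes (kept and discarded).
#' @param genome_lengths Tibble (`accession`, `genome_bp`) giving the
#'   total retained contig bp per genome (post [filter_assembly()]), or a
#'   list of [genome_record()]s.
#' @param metadata Optional metadata tibble (see [read_metadata_table()]
#'   for the expected columns).
#' @return Tibble of genome summaries.
#' @export
genome_summaries <- function(regions, genome_lengths, metadata = NULL) {
  if (is.list(genome_lengths) && !is.data.frame(genome_lengths) &&
      all(vapply(genome_lengths, inherits, logical(1), "genome_record"))) {
    genome_lengths <- tibble(
      accession = vapply(genome_lengths, `[[`, character(1), "accession"),
      genome_bp = vapply(genome_lengths, genome_length, numeric(1)))
  }
  genome_lengths <- as_tibble(genome_lengths)
  kept <- regions[regions$status == "kept", , drop = FALSE]
  per <- kept |>
    group_by(.data$accession) |>
    summarise(prophage_bp = sum(.data$end - .data$start + 1),
              n_prophages = dplyr::n(), .groups = "drop")
  out <- genome_lengths |>
    left_join(per, by = "accession") |>
    mutate(prophage_bp = dplyr::coalesce(.data$prophage_bp, 0),
           n_prophages = dplyr::coalesce(.data$n_prophages, 0L),
           genome_bp = .data$genome_bp - .data$prophage_bp,
           density = prophage_density(.data$prophage_bp, .data$genome_bp),
           concentration = .data$n_prophages,
           concentration_per_mbp = .data$n_prophages / (.data$genome_bp / 1e6),
           is_lysogen = .data$n_prophages >= 1)
  if (!is.null(metadata)) {
    md <- as_tibble(metadata)
    if ("assembly_accession" %in% names(md))
      md <- dplyr::rename(md, accession = "assembly_accession")
    if ("isolation_date" %in% names(md) && !"isolation_year" %in% names(md))
      md$isolation_year <- parse_isolation_date(md$isolation_date)
    if ("gtdb_lineage" %in% names(md) && !"phylum" %in% names(md)) {
      tax <- parse_gtdb_lineage(md$gtdb_lineage)
      md$phylum <- tax$phylum
      md$species <- tax$species
    }
    out <- left_join(out, md, by = "accession")
  }
  out
}

#' Per-genome summaries from planted truth
#'
#' The ground-truth counterpart of [genome_summaries()]: densities from
#' the simulator's planted (and retained) prophages rather than detector
#' calls.
#'
#' @param cohort A [generate_cohort()] result.
#' @return Tibble with one row per genome, metadata joined.
#' @export
truth_summaries <- function(cohort) {
  stopifnot(inherits(cohort, "prophage_cohort"))
  n_pro <- vapply(cohort$genome_meta$accession, function(a)
    sum(cohort$truth$accession == a & cohort$truth$retained), integer(1))
  out <- cohort$genome_meta |>
    mutate(density = .data$true_density,
           n_prophages = unname(n_pro),
           concentration = .data$n_prophages,
           concentration_per_mbp = .data$n_prophages / (.data$genome_bp / 1e6))
  md <- dplyr::rename(cohort$metadata, accession = "assembly_accession")
  md$isolation_year <- parse_isolation_date(md$isolation_date)
  tax <- parse_gtdb_lineage(md$gtdb_lineage)
  md$phylum <- tax$phylum
  md$species <- tax$species
  left_join(out, md, by = "accession")
}

#' Genome-size bin specification
#'
#' Left-closed, right-open bins over host genome size.
#'
#' @param minimum,maximum,step Bin range and width in bp (defaults 0,
#'   1.2e7, 1.4e6).
#' @return A `bin_spec` list.
#' @export
bin_spec <- function(minimum = 0, maximum = 1.2e7, step = 1.4e6) {
  if (step <= 0) stop("step must be positive")
  if (maximum <= minimum) stop("maximum must exceed minimum")
  # the default range is not a whole multiple of the step; the last bin is
  # simply truncated at `maximum`
  structure(list(minimum = minimum, maximum = maximum, step = step),
            class = "bin_spec")
}

#' Mean prophage density and concentration by genome-size bin
#'
#' Bins genomes by host genome size (left-closed, right-open) and reports
#' per-bin means of density and concentration. Genomes at or beyond the
#' bin maximum are excluded with a message. By default only lysogens are
#' aggregated.
#'
#' @param summaries Genome summaries ([genome_summaries()] or
#'   [truth_summaries()]).
#' @param bins A [bin_spec()].
#' @param lysogens_only Restrict to lysogens (default `TRUE`).
#' @return Tibble with one row per populated bin: `bin`, `bin_lo`,
#'   `bin_hi`, `n`, `mean_density`, `mean_concentration`,
#'   `mean_concentration_per_mbp`.
#' @export
bin_by_genome_size <- function(summaries, bins = bin_spec(),
                               lysogens_only = TRUE) {
  s <- as_tibble(summaries)
  if (!nrow(s)) stop("summaries is empty")
  if (lysogens_only) s <- filter(s, .data$is_lysogen)
  over <- s$genome_bp >= bins$maximum | s$genome_bp < bins$minimum
  if (any(over))
    message(sum(over), " genome(s) outside [", bins$minimum, ", ",
            bins$maximum, ") bp excluded from binning")
  s <- s[!over, ]
  s$bin <- floor((s$genome_bp - bins$minimum) / bins$step)
  s |>
    group_by(.data$bin) |>
    summarise(n = dplyr::n(),
              mean_density = mean(.data$density),
              mean_concentration = mean(.data$concentration),
              mean_concentration_per_mbp = mean(.data$concentration_per_mbp),
              .groups = "drop") |>
    mutate(bin_lo = bins$minimum + .data$bin * bins$step,
           bin_hi = bins$minimum + (.data$bin + 1) * bins$step) |>
    select("bin", "bin_lo", "bin_hi", "n", "mean_density",
           "mean_concentration", "mean_concentration_per_mbp") |>
    arrange(.data$bin)
}

#' Gaussian kernel density estimate with mode report
#'
#' A thin wrapper around [stats::density()] with a normal-reference
#' (Scott-type) bandwidth by default and a grid padded by six bandwidths,
#' so the estimate integrates to 1 within numerical tolerance. The argmax
#' of the curve is reported as the distribution mode (e.g. the ~20 kbp
#' prophage length peak, or the ~2.3 Mbp genome length peak).
#'
#' @param x Numeric sample (n >= 2, non-degenerate).
#' @param bw Bandwidth rule or numeric bandwidth (default `"nrd"`).
#' @param n_grid Grid size (default 1024).
#' @return A `prophage_kde` object: tibble of (`x`, `density`) with
#'   attributes `mode`, `bw`, `n`, `integral`.
#' @export
kde <- function(x, bw = "nrd", n_grid = 1024) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("kde needs at least 2 finite observations")
  if (stats::sd(x) == 0)
    stop("zero-variance sample; a histogram would be more honest than a KDE")
  d <- density(x, bw = bw, n = n_grid, cut = 6)
  integral <- sum(diff(d$x) * (head(d$y, -1) + tail(d$y, -1)) / 2)
  out <- tibble(x = d$x, density = d$y)
  structure(out, mode = d$x[which.max(d$y)], bw = d$bw, n = length(x),
            integral = integral, class = c("prophage_kde", class(out)))
}

#' @exportS3Method generics::glance
glance.prophage_kde <- function(x, ...) {
  tibble(mode = attr(x, "mode"), bw = attr(x, "bw"), n = attr(x, "n"),
         integral = attr(x, "integral"))
}

#' Ordinary least-squares trend
#'
#' Two-sided OLS slope test for trends such as prophage counts or
#' densities against isolation year.
#'
#' @param x,y Paired numeric observations (>= 3 finite pairs).
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`.
#' @export
trend_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite (x, y) pairs")
  if (stats::sd(x) == 0) stop("x is constant; no trend is estimable")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  tibble(slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = sm$r.squared,
         p_value = sm$coefficients[2, 4],
         n = length(x))
}

#' Compare prophage density between MAGs and isolates
#'
#' Group means and medians of genomic prophage density plus a two-sided
#' Mann-Whitney U (Wilcoxon rank-sum) test. MAG assembly loses prophages,
#' so MAGs are expected to sit well below isolates.
#'
#' @param summaries Genome summaries with `is_mag` and `density` columns.
#' @return A `mag_comparison` object: `groups` tibble (per-group n,
#'   mean, median), `p_value`, and `mag_to_isolate_ratio` of mean
#'   densities.
#' @export
mag_isolate_comparison <- function(summaries) {
  s <- as_tibble(summaries)
  if (!all(c("is_mag", "density") %in% names(s)))
    stop("summaries must carry 'is_mag' and 'density' columns")
  s <- filter(s, !is.na(.data$is_mag))
  if (!any(s$is_mag) || !any(!s$is_mag))
    stop("both MAG and isolate groups must be non-empty")
  groups <- s |>
    group_by(group = ifelse(.data$is_mag, "MAG", "isolate")) |>
    summarise(n = dplyr::n(), mean_density = mean(.data$density),
              median_density = median(.data$density), .groups = "drop")
  p <- if (nrow(s) <= 2) 1 else
    suppressWarnings(wilcox.test(density ~ is_mag, data = s,
                                 exact = FALSE)$p.value)
  if (!is.finite(p)) p <- 1   # fully tied samples carry no evidence
  ratio <- groups$mean_density[groups$group == "MAG"] /
    groups$mean_density[groups$group == "isolate"]
  structure(list(groups = groups, p_value = p,
                 mag_to_isolate_ratio = unname(ratio)),
            class = "mag_comparison")
}

#' @export
print.mag_comparison <- function(x, ...) {
  cat("MAG vs isolate prophage density\n")
  print(as.data.frame(x$groups), row.names = FALSE)
  cat(sprintf("  mean ratio (MAG/isolate) = %.3f, Mann-Whitney p = %.3g\n",
              x$mag_to_isolate_ratio, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mag_comparison <- function(x, ...) x$groups

#' @exportS3Method generics::glance
glance.mag_comparison <- function(x, ...) {
  tibble(mag_to_isolate_ratio = x$mag_to_isolate_ratio, p.value = x$p_value)
}

#' Verified-fraction analysis across phyla
#'
#' Aggregates proposed (kept + discarded) and verified prophage bp per
#' phylum and regresses the verified fraction on the proposed bp (is the
#' database-verified content independent of how much the detector
#' proposes?) and, when a first-described year table is supplied, on the
#' year the phylum was first described.
#'
#' @param regions Detector output carrying `verified_bp_fraction`, with a
#'   `phylum` column (join metadata beforehand).
#' @param phylum_first_described Optional tibble (`phylum`, `year`).
#' @return List with `per_phylum` (tibble: proposed bp, verified bp,
#'   fraction), `vs_proposed_bp` and (optionally) `vs_year` regression
#'   rows as in [trend_regression()].
#' @export
verified_fraction_analysis <- function(regions, phylum_first_described = NULL) {
  r <- as_tibble(regions)
  if (!"phylum" %in% names(r))
    stop("regions must carry a 'phylum' column (join metadata first)")
  per <- r |>
    mutate(bp = .data$end - .data$start + 1,
           vbp = .data$verified_bp_fraction * .data$bp) |>
    group_by(.data$phylum) |>
    summarise(proposed_bp = sum(.data$bp), verified_bp = sum(.data$vbp),
              n_regions = dplyr::n(), .groups = "drop") |>
    mutate(fraction = .data$verified_bp / .data$proposed_bp)
  out <- list(per_phylum = per)
  if (nrow(per) >= 3 && stats::sd(per$proposed_bp) > 0)
    out$vs_proposed_bp <- trend_regression(per$proposed_bp, per$fraction)
  if (!is.null(phylum_first_described)) {
    j <- left_join(per, as_tibble(phylum_first_described), by = "phylum")
    if (sum(is.finite(j$year)) >= 3)
      out$vs_year <- trend_regression(j$year, j$fraction)
  }
  out
}
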