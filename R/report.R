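#' Pipeline run configuration
#'
#' Every tunable detector and pipeline parameter in one validated,
#' serialisable list. Defaults: keep regions of 5+ genes, contigs of
#' 5,000+ bp, at least 1 annotated phage gene (or a database hit), 2,000
#' bp repeat-search flanks, 10 bp minimum repeats, 500 random-forest
#' trees, 30-ORF windows.
#'
#' @param number Minimum phage-predicted genes per kept region.
#' @param min_contig_len Minimum analysed contig length (bp).
#' @param phage_genes Annotated phage genes required by verification.
#' @param extra_dna Repeat-search flank width (bp).
#' @param min_repeat_len Minimum flanking repeat length (bp).
#' @param randomforest_trees Trees in the classifier forest.
#' @param window_size ORF window for the metrics.
#' @param threads Worker threads honoured by callers (results are
#'   thread-count invariant; the reference implementation is serial).
#' @param metrics Feature set (fixed: the five ORF metrics).
#' @param training_set Optional path of a saved training table.
#' @param phmms Optional profile-HMM file for verification.
#' @param gap_tolerance Host-predicted ORFs tolerated inside a run.
#' @param kmer_k Marker k-mer length.
#' @param min_orf_len Minimum called ORF length (bp) for FASTA input.
#' @param threshold Classifier decision threshold.
#' @param annotation_tokens Phage annotation tokens.
#' @param seed Global pipeline seed.
#' @return A validated `prophage_config` list.
#' @export
run_config <- function(number = 5,
                       min_contig_len = 5000,
                       phage_genes = 1,
                       extra_dna = 2000,
                       min_repeat_len = 10,
                       randomforest_trees = 500,
                       window_size = 30,
                       threads = 2,
                       metrics = classifier_features,
                       training_set = NULL,
                       phmms = NULL,
                       gap_tolerance = 2,
                       kmer_k = 12,
                       min_orf_len = 90,
                       threshold = 0.5,
                       annotation_tokens = default_phage_tokens(),
                       seed = 1) {
  cfg <- list(number = number, min_contig_len = min_contig_len,
              phage_genes = phage_genes, extra_dna = extra_dna,
              min_repeat_len = min_repeat_len,
              randomforest_trees = randomforest_trees,
              window_size = window_size, threads = threads,
              metrics = metrics, training_set = training_set, phmms = phmms,
              gap_tolerance = gap_tolerance, kmer_k = kmer_k,
              min_orf_len = min_orf_len, threshold = threshold,
              annotation_tokens = annotation_tokens, seed = seed)
  validate_config(cfg)
}

config_fields <- function() {
  c("number", "min_contig_len", "phage_genes", "extra_dna", "min_repeat_len",
    "randomforest_trees", "window_size", "threads", "metrics", "training_set",
    "phmms", "gap_tolerance", "kmer_k", "min_orf_len", "threshold",
    "annotation_tokens", "seed")
}

validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), config_fields())
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (f in c("number", "min_contig_len", "phage_genes", "extra_dna",
              "min_repeat_len", "randomforest_trees", "window_size",
              "gap_tolerance", "kmer_k", "min_orf_len", "seed", "threads")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0)
      stop("configuration field '", f, "' must be a non-negative number")
  }
  if (cfg$threshold < 0 || cfg$threshold > 1)
    stop("threshold must be a probability")
  structure(cfg, class = "prophage_config")
}

#' Write and read a configuration echo
#'
#' The YAML round-trip is the reproducibility contract: re-running a
#' pipeline from the echoed configuration (same seed) reproduces the run.
#'
#' @param config A [run_config()] list.
#' @param path YAML file path.
#' @return `path` invisibly ([write_config()]); a validated
#'   `prophage_config` ([read_config()]).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "prophage_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), config_fields())
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  full <- unclass(run_config())
  for (f in names(cfg)) full[f] <- cfg[f]   # [f] keeps explicit NULLs
  validate_config(full)
}

#' Write a machine-readable run log
#'
#' Records the seed, package and R versions, and md5 digests of input
#' files next to the configuration echo.
#'
#' @param path Log file path (YAML).
#' @param config The `prophage_config` used.
#' @param inputs Character vector of input file paths to digest.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, config, inputs = character()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  yaml::write_yaml(list(
    seed = config$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("prophagr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_digests = digests,
    config = unclass(config)), path)
  invisible(path)
}

#' Cohort roll-up summary
#'
#' Counts of genomes processed, lysogens, kept prophages and the
#' dereplicated subset size; with truth supplied, region-level
#' sensitivity and precision are appended. Counts are additive over
#' cohort shards.
#'
#' @param summaries Genome summaries.
#' @param regions Optional detector output (for kept/discarded counts).
#' @param truth Optional planted truth (adds recovery columns).
#' @param max_contigs Contig-count threshold used in filtering (for the
#'   reported "< max_contigs" count when a `n_contigs` column exists).
#' @return One-row tibble of counts (and recovery columns when truth is
#'   given).
#' @export
cohort_summary <- function(summaries, regions = NULL, truth = NULL,
                           max_contigs = 100) {
  s <- as_tibble(summaries)
  out <- tibble(
    n_genomes = nrow(s),
    n_under_contig_cap = if ("n_contigs" %in% names(s))
      sum(s$n_contigs < max_contigs) else nrow(s),
    n_lysogens = if (nrow(s)) sum(s$is_lysogen) else 0L,
    n_prophages_kept = if (!is.null(regions))
      sum(regions$status == "kept") else if (nrow(s)) sum(s$n_prophages) else 0L,
    n_species = if ("species" %in% names(s))
      dplyr::n_distinct(s$species[!is.na(s$species)]) else NA_integer_)
  if (!is.null(truth) && !is.null(regions)) {
    rec <- region_recovery(regions, truth)
    out <- dplyr::bind_cols(out, rec[, c("sensitivity", "precision")])
  }
  out
}

#' Per-phylum density table and tree annotation export
#'
#' Mean, standard deviation and their ratio per phylum, plus an optional
#' label-to-value annotation table and a pruned Newick tree for external
#' tree viewers.
#'
#' @param summaries Genome summaries with `phylum` and `density`.
#' @param tree Optional [ape::phylo] tree whose tip labels are phylum
#'   names; it is pruned to the observed phyla.
#' @param annotation_path,tree_path Optional output paths (TSV/Newick).
#' @return List: `table` (per-phylum tibble) and `tree` (pruned, or
#'   `NULL`).
#' @export
phylum_density_export <- function(summaries, tree = NULL,
                                  annotation_path = NULL, tree_path = NULL) {
  s <- filter(as_tibble(summaries), !is.na(.data$phylum))
  tab <- s |>
    group_by(.data$phylum) |>
    summarise(n = dplyr::n(), mean_density = mean(.data$density),
              sd_density = stats::sd(.data$density), .groups = "drop") |>
    mutate(sd_density = ifelse(is.na(.data$sd_density), 0, .data$sd_density),
           sd_to_mean = ifelse(.data$mean_density > 0,
                               .data$sd_density / .data$mean_density, NA_real_))
  pruned <- NULL
  if (!is.null(tree)) {
    keep <- intersect(tree$tip.label, tab$phylum)
    if (length(keep) >= 2) pruned <- ape::keep.tip(tree, keep)
    if (!is.null(tree_path) && !is.null(pruned))
      ape::write.tree(pruned, tree_path)
  }
  if (!is.null(annotation_path))
    write.table(tab[, c("phylum", "mean_density")], annotation_path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  list(table = tab, tree = pruned)
}

#' Country-by-phylum genome count matrix
#'
#' The sampling-effort surface: genome counts per phylum and country,
#' rows and columns sorted by marginal totals, optionally truncated to
#' the top contributors. Missing countries are routed to an `"unknown"`
#' column; genomes without a phylum label are excluded.
#'
#' @param summaries Genome summaries with `phylum` and `country`.
#' @param top_phyla,top_countries Truncation (defaults 26 and 15; `Inf`
#'   disables).
#' @return Integer matrix (phyla x countries).
#' @export
country_phylum_matrix <- function(summaries, top_phyla = 26,
                                  top_countries = 15) {
  s <- filter(as_tibble(summaries), !is.na(.data$phylum))
  if (!nrow(s))
    return(matrix(integer(0), 0, 0))
  s$country <- ifelse(is.na(s$country), "unknown", s$country)
  tab <- table(s$phylum, s$country)
  tab <- tab[order(-rowSums(tab)), order(-colSums(tab)), drop = FALSE]
  tab <- tab[seq_len(min(nrow(tab), top_phyla)),
             seq_len(min(ncol(tab), top_countries)), drop = FALSE]
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}
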