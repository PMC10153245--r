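#' Apply assembly quality filters
#'
#' Mirrors the corpus quality control: an assembly with `max_contigs` or
#' more contigs is excluded outright; otherwise contigs shorter than
#' `min_contig_len` are dropped from the detection universe. The boundary
#' is inclusive: a contig of exactly `min_contig_len` bp is retained.
#'
#' @param genome A [genome_record()].
#' @param max_contigs Exclude the whole assembly at this contig count
#'   (default 100, i.e. "fewer than 100 contigs" pass).
#' @param min_contig_len Minimum retained contig length in bp (default
#'   5000).
#' @return A list with elements `genome` (the filtered record, or `NULL`
#'   when excluded), `excluded` (flag), `reason`, and `dropped` (tibble of
#'   dropped contigs with lengths).
#' @export
filter_assembly <- function(genome, max_contigs = 100, min_contig_len = 5000) {
  stopifnot(inherits(genome, "genome_record"))
  empty_drop <- tibble(contig_id = character(), length = integer())
  if (nrow(genome$contig_lengths) >= max_contigs) {
    return(list(genome = NULL, excluded = TRUE,
                reason = sprintf("%d contigs (>= %d)",
                                 nrow(genome$contig_lengths), max_contigs),
                dropped = empty_drop))
  }
  short <- genome$contig_lengths$length < min_contig_len
  dropped <- genome$contig_lengths[short, ]
  if (any(short)) {
    keep_ids <- genome$contig_lengths$contig_id[!short]
    if (!length(keep_ids)) {
      return(list(genome = NULL, excluded = TRUE,
                  reason = "no contig reaches min_contig_len",
                  dropped = dropped))
    }
    genome <- genome_record(
      genome$accession,
      contigs = if (!is.null(genome$contigs)) genome$contigs[keep_ids] else NULL,
      cds = genome$cds[genome$cds$contig_id %in% keep_ids, ],
      source = genome$source,
      contig_lengths = if (is.null(genome$contigs))
        genome$contig_lengths[!short, ] else NULL)
  }
  list(genome = genome, excluded = FALSE, reason = NA_character_,
       dropped = dropped)
}

#' Convert an isolation-date string to a decimal year
#'
#' Total and vectorised: ISO dates (`"2013-06-15"`), year-month
#' (`"2013-06"`) and bare years (`"2013"`) map to a decimal year; anything
#' else (including `NA`) maps to `NA` rather than raising. A date maps to
#' `year + (day_of_year - 1) / 365`; bare years map to mid-year
#' (`+ 0.5`) and year-months to the 15th of the month, so the granularity
#' of the input introduces no systematic bias. Years outside
#' `[1800, current year + 1]` are treated as unparseable.
#'
#' @param raw Character vector of raw date strings.
#' @return Numeric vector of decimal years (`NA` where unparseable).
#' @export
parse_isolation_date <- function(raw) {
  one <- function(s) {
    if (is.na(s)) return(NA_real_)
    s <- trimws(s)
    # tolerate a time suffix
    s <- sub("[T ].*$", "", s)
    ymd <- regmatches(s, regexec("^([0-9]{4})-([0-9]{1,2})-([0-9]{1,2})$", s))[[1]]
    ym <- regmatches(s, regexec("^([0-9]{4})-([0-9]{1,2})$", s))[[1]]
    y <- regmatches(s, regexec("^([0-9]{4})$", s))[[1]]
    dec <- NA_real_
    if (length(ymd)) {
      d <- suppressWarnings(as.Date(sprintf("%s-%02d-%02d", ymd[2],
                                            as.integer(ymd[3]),
                                            as.integer(ymd[4]))))
      if (!is.na(d))
        dec <- as.integer(ymd[2]) + (as.integer(format(d, "%j")) - 1) / 365
    } else if (length(ym)) {
      d <- suppressWarnings(as.Date(sprintf("%s-%02d-15", ym[2],
                                            as.integer(ym[3]))))
      if (!is.na(d))
        dec <- as.integer(ym[2]) + (as.integer(format(d, "%j")) - 1) / 365
    } else if (length(y)) {
      dec <- as.integer(y[2]) + 0.5
    }
    yr <- floor(dec)
    if (!is.na(dec) &&
        (yr < 1800 || yr > as.integer(format(Sys.Date(), "%Y")) + 1))
      dec <- NA_real_
    dec
  }
  vapply(as.character(raw), one, numeric(1), USE.NAMES = FALSE)
}

#' Split GTDB lineage strings into rank columns
#'
#' @param lineage Character vector of rank-prefixed lineage strings
#'   (`d__...;p__...;...;s__...`).
#' @return Tibble with columns `domain`, `phylum`, `class`, `order`,
#'   `family`, `genus`, `species` (`NA` where a rank is absent or empty).
#' @export
parse_gtdb_lineage <- function(lineage) {
  ranks <- c(d = "domain", p = "phylum", c = "class", o = "order",
             f = "family", g = "genus", s = "species")
  out <- lapply(ranks, function(r) rep(NA_character_, length(lineage)))
  names(out) <- ranks
  for (i in seq_along(lineage)) {
    if (is.na(lineage[i])) next
    parts <- strsplit(lineage[i], ";")[[1]]
    for (p in parts) {
      p <- trimws(p)
      m <- regmatches(p, regexec("^([a-z])__(.*)$", p))[[1]]
      if (length(m) == 3 && m[2] %in% names(ranks) && nzchar(m[3]))
        out[[ranks[m[2]]]][i] <- m[3]
    }
  }
  as_tibble(out)
}

#' Keep one genome per species
#'
#' Removes database sampling bias by keeping exactly one randomly chosen
#' genome per distinct species label. Rows whose species cannot be
#' determined (missing lineage or empty `s__` field) are excluded.
#'
#' @param summaries Data frame with one row per genome carrying either a
#'   `species` column or a `gtdb_lineage` column.
#' @param seed Optional seed controlling the random choice.
#' @return The dereplicated subset (tibble), one row per species.
#' @export
dereplicate_by_species <- function(summaries, seed = NULL) {
  summaries <- as_tibble(summaries)
  if (!nrow(summaries)) return(summaries)
  sp <- if ("species" %in% names(summaries)) summaries$species
        else if ("gtdb_lineage" %in% names(summaries))
          parse_gtdb_lineage(summaries$gtdb_lineage)$species
        else stop("summaries must carry a 'species' or 'gtdb_lineage' column")
  keep <- !is.na(sp) & nzchar(sp)
  summaries <- summaries[keep, ]
  sp <- sp[keep]
  if (!nrow(summaries)) return(summaries)
  with_seed(seed, {
    picked <- unlist(lapply(split(seq_along(sp), sp), function(ix)
      if (length(ix) == 1) ix else sample(ix, 1)))
    summaries[sort(unname(picked)), ]
  })
}

#' Read a tab-separated metadata table
#'
#' Expected columns: `assembly_accession`, `isolation_date`, `country`,
#' `gtdb_lineage`, `is_mag` (extra columns pass through). Duplicate rows
#' per accession keep the first occurrence. Dates are normalised with
#' [parse_isolation_date()]; country labels are canonicalised by trimming
#' and collapsing internal whitespace.
#'
#' @param path TSV file path.
#' @return Tibble with one row per accession, including derived
#'   `isolation_year` and taxonomy rank columns.
#' @export
read_metadata_table <- function(path) {
  md <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             na.strings = c("NA", "")))
  if (!"assembly_accession" %in% names(md))
    stop("metadata table must have an 'assembly_accession' column")
  md <- md[!duplicated(md$assembly_accession), ]
  if ("isolation_date" %in% names(md))
    md$isolation_year <- parse_isolation_date(md$isolation_date)
  if ("country" %in% names(md))
    md$country <- canonical_country(md$country)
  if ("gtdb_lineage" %in% names(md)) {
    tax <- parse_gtdb_lineage(md$gtdb_lineage)
    md$phylum <- tax$phylum
    md$species <- tax$species
  }
  if ("is_mag" %in% names(md)) md$is_mag <- as.logical(md$is_mag)
  md
}

canonical_country <- function(x) {
  x <- gsub("[[:space:]]+", " ", trimws(as.character(x)))
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

#' Load a simulated cohort directory
#'
#' Reads back a directory written by [generate_cohort()]/[write_cohort()]
#' (GenBank files plus `metadata.tsv`, `truth.tsv` and, when present,
#' `marker_kmers.txt`) into a `prophage_cohort`.
#'
#' @param dir Cohort directory.
#' @return A `prophage_cohort` (without the originating spec).
#' @export
read_cohort_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.gbff$", full.names = TRUE)
  if (!length(files)) stop("no .gbff files found in '", dir, "'")
  md_path <- file.path(dir, "metadata.tsv")
  metadata <- if (file.exists(md_path)) {
    m <- as_tibble(read.delim(md_path, stringsAsFactors = FALSE,
                              na.strings = c("NA", "")))
    if ("is_mag" %in% names(m)) m$is_mag <- as.logical(m$is_mag)
    m
  } else {
    tibble(assembly_accession = sub("\\.gbff$", "", basename(files)))
  }
  mags <- if ("is_mag" %in% names(metadata))
    metadata$assembly_accession[metadata$is_mag %in% TRUE] else character()
  genomes <- lapply(files, function(f) {
    g <- read_genbank(f)
    g$source <- if (g$accession %in% mags) "MAG" else "isolate"
    g
  })
  tr_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(tr_path)) {
    as_tibble(read.delim(tr_path, stringsAsFactors = FALSE))
  } else {
    tibble(accession = character(), contig_id = character(),
           start = integer(), end = integer(), length = integer(),
           component = integer(), retained = logical())
  }
  mk_path <- file.path(dir, "marker_kmers.txt")
  marker_set <- if (file.exists(mk_path)) readLines(mk_path) else character()
  acc <- vapply(genomes, `[[`, character(1), "accession")
  glen <- vapply(genomes, genome_length, numeric(1))
  planted <- vapply(acc, function(a)
    sum(truth$length[truth$accession == a & truth$retained]), numeric(1))
  genome_meta <- tibble(accession = acc,
                        genome_bp = unname(glen - planted),
                        prophage_bp = unname(planted),
                        true_density = unname(planted / (glen - planted)),
                        is_lysogen = unname(planted > 0),
                        planted = unname(planted > 0))
  structure(list(genomes = genomes, metadata = metadata, truth = truth,
                 genome_meta = genome_meta, marker_set = marker_set,
                 spec = NULL),
            class = "prophage_cohort")
}
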