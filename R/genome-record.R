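#' Assemble a genome record
#'
#' The unit consumed by the detector and the landscape statistics: a set of
#' contigs plus their protein-coding features. Coordinates are 1-based and
#' inclusive at both ends throughout the package (GFF-style).
#'
#' @param accession Assembly accession string.
#' @param contigs Named character vector or [Biostrings::DNAStringSet] of
#'   contig sequences. May be `NULL` for coordinate-only records (as emitted
#'   by [generate_cohort()] with `sequences = FALSE`), in which case
#'   `contig_lengths` must be given.
#' @param cds Tibble of protein-coding features with columns `contig_id`,
#'   `start`, `end`, `strand` (`"+"`/`"-"`) and `annotation` (free text).
#'   A `length` column is derived as `end - start + 1`.
#' @param source One of `"isolate"`, `"MAG"`, `"unknown"`.
#' @param contig_lengths Optional tibble (`contig_id`, `length`) used when
#'   `contigs` is `NULL`.
#'
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(accession, contigs = NULL, cds = NULL,
                          source = "unknown", contig_lengths = NULL) {
  source <- match.arg(source, c("isolate", "MAG", "unknown"))
  if (!is.null(contigs)) {
    if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(toupper(contigs))
    if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
      stop("contigs must be uniquely named")
    contig_lengths <- tibble(
      contig_id = names(contigs),
      length = Biostrings::width(contigs)
    )
  } else if (is.null(contig_lengths)) {
    stop("either contigs or contig_lengths must be supplied")
  }
  if (is.null(cds)) {
    cds <- tibble(contig_id = character(), start = integer(), end = integer(),
                  strand = character(), annotation = character())
  }
  cds <- as_tibble(cds)
  cds$length <- cds$end - cds$start + 1L
  bad <- !cds$contig_id %in% contig_lengths$contig_id
  if (any(bad)) stop("CDS features reference unknown contigs: ",
                     paste(unique(cds$contig_id[bad]), collapse = ", "))
  lens <- setNames(contig_lengths$length, contig_lengths$contig_id)
  out_of_bounds <- cds$start < 1 | cds$end > lens[cds$contig_id] | cds$start > cds$end
  if (any(out_of_bounds)) {
    warning(sum(out_of_bounds), " CDS feature(s) with coordinates outside ",
            "their contig were dropped")
    cds <- cds[!out_of_bounds, ]
  }
  structure(
    list(accession = accession, contigs = contigs,
         contig_lengths = contig_lengths, cds = cds, source = source),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$accession, "\n", sep = "")
  cat("  contigs: ", nrow(x$contig_lengths),
      " (", format(sum(x$contig_lengths$length), big.mark = ","), " bp",
      if (is.null(x$contigs)) ", coordinates only" else "", ")\n", sep = "")
  cat("  CDS features: ", nrow(x$cds), "\n", sep = "")
  cat("  source: ", x$source, "\n", sep = "")
  invisible(x)
}

#' Total genome length of a record
#'
#' @param genome A `genome_record`.
#' @return Total contig length in bp.
#' @export
genome_length <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  sum(genome$contig_lengths$length)
}

# contig sequence as a plain character scalar
contig_seq <- function(genome, contig_id) {
  if (is.null(genome$contigs))
    stop("genome record '", genome$accession, "' carries no sequence ",
         "(generated with sequences = FALSE?)")
  as.character(genome$contigs[[contig_id]])
}
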