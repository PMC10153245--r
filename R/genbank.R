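#' Write a genome record as a GenBank flat file
#'
#' One LOCUS record per contig, with `source` and `CDS` features (1-based
#' inclusive coordinates, `complement(..)` for the minus strand) and the
#' sequence in a standard ORIGIN block.
#'
#' @param genome A [genome_record()] carrying sequence.
#' @param path Output file path (conventionally `.gbff`).
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  stopifnot(inherits(genome, "genome_record"))
  if (is.null(genome$contigs))
    stop("cannot write a coordinate-only record as GenBank")
  con <- file(path, "w")
  on.exit(close(con))
  tag_n <- 0L
  for (cid in names(genome$contigs)) {
    seq <- tolower(as.character(genome$contigs[[cid]]))
    len <- nchar(seq)
    writeLines(sprintf(
      "LOCUS       %-16s%12d bp    DNA     linear   BCT 01-JAN-2024",
      cid, len), con)
    writeLines(sprintf("DEFINITION  synthetic bacterial genome %s contig %s.",
                       genome$accession, cid), con)
    writeLines(sprintf("ACCESSION   %s", genome$accession), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", len), con)
    writeLines("                     /organism=\"synthetic bacterium\"", con)
    writeLines("                     /mol_type=\"genomic DNA\"", con)
    cds <- genome$cds[genome$cds$contig_id == cid, ]
    if (nrow(cds)) {
      cds <- arrange(cds, .data$start)
      for (i in seq_len(nrow(cds))) {
        tag_n <- tag_n + 1L
        loc <- sprintf("%d..%d", cds$start[i], cds$end[i])
        if (cds$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
        writeLines(sprintf("     CDS             %s", loc), con)
        writeLines(sprintf("                     /locus_tag=\"%s_%05d\"",
                           gsub("[^A-Za-z0-9]", "", genome$accession), tag_n), con)
        writeLines(sprintf("                     /product=\"%s\"",
                           cds$annotation[i]), con)
      }
    }
    writeLines("ORIGIN", con)
    starts <- seq(1, len, by = 60)
    chunk <- function(s) {
      line <- substr(seq, s, min(s + 59, len))
      m <- nchar(line)
      paste(substring(line, seq(1, m, by = 10), pmin(seq(10, m + 9, by = 10), m)),
            collapse = " ")
    }
    writeLines(sprintf("%9d %s", starts, vapply(starts, chunk, character(1))),
               con)
    writeLines("//", con)
  }
  invisible(path)
}

#' Read a GenBank flat file into a genome record
#'
#' Parses a (possibly multi-record) GenBank flat file: one LOCUS record per
#' contig, CDS features with strand and product text. Compound
#' (`join(...)`) locations are skipped with a warning; CDS features whose
#' coordinates fall outside their contig are dropped with a warning.
#' Sequences are uppercased.
#'
#' @param path Path to a `.gbff`/`.gb` file.
#' @param accession Override for the record accession (defaults to the
#'   first ACCESSION line, or the file name).
#' @param source Genome source flag (`"isolate"`, `"MAG"`, `"unknown"`).
#' @return A [genome_record()].
#' @export
read_genbank <- function(path, accession = NULL, source = "unknown") {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(startsWith(lines, "LOCUS")))
    stop("'", path, "' does not look like a GenBank flat file (no LOCUS record)")
  rec_start <- which(startsWith(lines, "LOCUS"))
  rec_end <- which(trimws(lines) == "//")
  if (length(rec_end) < length(rec_start))
    rec_end <- c(rec_end, length(lines))
  contigs <- list()
  cds <- list()
  acc <- accession
  for (r in seq_along(rec_start)) {
    block <- lines[rec_start[r]:rec_end[r]]
    locus_fields <- strsplit(trimws(block[1]), "[[:space:]]+")[[1]]
    if (length(locus_fields) < 2)
      stop("unparseable LOCUS line in record ", r, " of '", path, "'")
    cid <- locus_fields[2]
    if (is.null(acc)) {
      acc_line <- grep("^ACCESSION", block, value = TRUE)
      acc <- if (length(acc_line))
        strsplit(trimws(acc_line[1]), "[[:space:]]+")[[1]][2]
      else basename(path)
    }
    fst <- grep("^FEATURES", block)
    ost <- grep("^ORIGIN", block)
    if (!length(ost))
      stop("record '", cid, "' in '", path, "' has no ORIGIN block")
    seq <- toupper(gsub("[^A-Za-z]", "",
                        paste(block[(ost[1] + 1):(length(block) - 1)],
                              collapse = "")))
    if (!nchar(seq))
      stop("record '", cid, "' in '", path, "' has an empty sequence")
    contigs[[cid]] <- seq
    if (length(fst)) {
      feat_lines <- block[(fst[1] + 1):(ost[1] - 1)]
      is_new <- !grepl("^[[:space:]]{21}", feat_lines) &
        grepl("^[[:space:]]{1,10}[A-Za-z]", feat_lines)
      idx <- cumsum(is_new)
      for (f in split(feat_lines, idx)) {
        key <- strsplit(trimws(f[1]), "[[:space:]]+")[[1]]
        if (length(key) < 2 || key[1] != "CDS") next
        loc <- key[2]
        # location may continue on following lines until a qualifier starts
        qstart <- match(TRUE, grepl("^[[:space:]]*/", f[-1])) %||% NA
        if (is.na(qstart)) qstart <- length(f)
        if (qstart > 1)
          loc <- paste0(loc, paste(trimws(f[1 + seq_len(qstart - 1)]),
                                   collapse = ""))
        if (grepl("join|order", loc)) {
          warning("skipping compound location '", loc, "' in '", cid, "'")
          next
        }
        strand <- if (grepl("complement", loc)) "-" else "+"
        nums <- suppressWarnings(
          as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]]))
        if (length(nums) != 2 || anyNA(nums)) {
          warning("skipping unparseable location '", loc, "' in '", cid, "'")
          next
        }
        qual <- paste(trimws(f), collapse = " ")
        prod <- regmatches(qual, regexpr('/product="[^"]*"', qual))
        prod <- if (length(prod))
          sub('/product="', "", sub('"$', "", prod)) else ""
        cds[[length(cds) + 1L]] <- tibble(
          contig_id = cid, start = nums[1], end = nums[2],
          strand = strand, annotation = prod)
      }
    }
  }
  genome_record(acc %||% basename(path),
                contigs = unlist(contigs),
                cds = if (length(cds)) bind_rows(cds) else NULL,
                source = source)
}
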