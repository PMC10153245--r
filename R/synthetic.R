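#' Specification for a synthetic lysogen cohort
#'
#' Collects every knob of the cohort generator. The defaults describe the
#' landscape the statistics in this package are designed around: host
#' genomes with a length mode of 2.3 Mbp, prophage cassettes with a length
#' mode of 20 kbp and a tailed decay, a genomic prophage density of 2.4%
#' (prophage bp per bp of host DNA, host length excluding the prophages),
#' and 94% of genomes lysogenic.
#'
#' @param n_genomes Number of genomes in the cohort.
#' @param genome_len_mode,genome_len_spread Mode and standard deviation (bp)
#'   of the log-normal host genome length distribution.
#' @param genome_len_range Optional `c(min, max)` bp; when given, genome
#'   lengths are drawn uniformly from this range instead (useful for
#'   spanning several genome-size bins evenly).
#' @param backbone_gc GC fraction of the host backbone, in (0, 1).
#' @param prophage_len_mode,prophage_len_sd Mode and standard deviation (bp)
#'   of the single-component log-normal prophage length distribution.
#' @param prophage_len_components Optional per-taxon mixture: a data frame
#'   with columns `weight`, `mode`, `sd` (weights must sum to 1). Overrides
#'   the single-component parameters.
#' @param target_density Genomic prophage density to plant (prophage bp /
#'   host bp). Default 0.024.
#' @param lysogen_fraction Fraction of genomes that receive prophages.
#' @param marker_kmer_count,kmer_k Size of the synthetic phage marker k-mer
#'   set and the k used throughout (detector scoring uses the same k).
#' @param att_repeat_len Length (bp) of the exact direct repeat planted at
#'   both cassette ends (the attL/attR pair).
#' @param mag_fraction Fraction of genomes flagged as metagenome-assembled
#'   (MAG); those are post-processed by [mag_degrade()].
#' @param mag_loss_prob Per-prophage probability that a MAG loses a planted
#'   prophage during assembly (default 2/3, i.e. a 3-fold density drop in
#'   expectation).
#' @param year_range Inclusive isolation-year range for metadata.
#' @param country_pool,taxon_pool Label pools for metadata; taxa are
#'   rank-prefixed GTDB-style lineage strings.
#' @param phage_product_rate Fraction of cassette genes whose product text
#'   contains a recognisable phage token.
#' @param min_cassette_len Smallest prophage cassette the generator will
#'   plant (bp).
#' @param seed Integer seed; all cohort randomness flows from it.
#'
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genomes = 50,
                           genome_len_mode = 2.3e6,
                           genome_len_spread = 4e5,
                           genome_len_range = NULL,
                           backbone_gc = 0.5,
                           prophage_len_mode = 2e4,
                           prophage_len_sd = 8e3,
                           prophage_len_components = NULL,
                           target_density = 0.024,
                           lysogen_fraction = 0.94,
                           marker_kmer_count = 200,
                           kmer_k = 12,
                           att_repeat_len = 12,
                           mag_fraction = 0,
                           mag_loss_prob = 2 / 3,
                           year_range = c(1995, 2021),
                           country_pool = default_country_pool(),
                           taxon_pool = default_taxon_pool(),
                           phage_product_rate = 0.3,
                           min_cassette_len = 3000,
                           seed = 1) {
  spec <- list(
    n_genomes = as.integer(n_genomes),
    genome_len_mode = genome_len_mode,
    genome_len_spread = genome_len_spread,
    genome_len_range = genome_len_range,
    backbone_gc = backbone_gc,
    prophage_len_mode = prophage_len_mode,
    prophage_len_sd = prophage_len_sd,
    prophage_len_components = prophage_len_components,
    target_density = target_density,
    lysogen_fraction = lysogen_fraction,
    marker_kmer_count = as.integer(marker_kmer_count),
    kmer_k = as.integer(kmer_k),
    att_repeat_len = as.integer(att_repeat_len),
    mag_fraction = mag_fraction,
    mag_loss_prob = mag_loss_prob,
    year_range = year_range,
    country_pool = country_pool,
    taxon_pool = taxon_pool,
    phage_product_rate = phage_product_rate,
    min_cassette_len = min_cassette_len,
    seed = as.integer(seed)
  )
  for (f in c("target_density", "lysogen_fraction", "mag_fraction",
              "mag_loss_prob", "phage_product_rate")) {
    v <- spec[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(f, " must be a fraction in [0, 1]")
  }
  if (spec$backbone_gc <= 0 || spec$backbone_gc >= 1)
    stop("backbone_gc must lie strictly inside (0, 1)")
  if (spec$n_genomes < 1) stop("n_genomes must be at least 1")
  if (spec$prophage_len_mode < spec$min_cassette_len)
    stop("prophage_len_mode must be at least min_cassette_len (",
         spec$min_cassette_len, " bp, >= 5 genes)")
  if (!is.null(spec$prophage_len_components)) {
    cmp <- as_tibble(spec$prophage_len_components)
    stopifnot(all(c("weight", "mode", "sd") %in% names(cmp)))
    if (abs(sum(cmp$weight) - 1) > 1e-8)
      stop("prophage length mixture weights must sum to 1")
    spec$prophage_len_components <- cmp
  }
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", x$n_genomes, " genomes, density ",
      x$target_density, ", lysogen fraction ", x$lysogen_fraction,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

default_country_pool <- function() {
  c("USA", "China", "United Kingdom", "Australia", "Germany",
    "Brazil", "India", "South Africa")
}

default_taxon_pool <- function() {
  phyla <- c("Pseudomonadota", "Bacillota", "Campylobacterota", "Bacteroidota")
  unlist(lapply(seq_along(phyla), function(i) {
    sprintf("d__Bacteria;p__%s;c__SynClass%d;o__SynOrder%d;f__SynFamily%d;g__SynGenus%d;s__SynGenus%d species%d",
            phyla[i], i, i, i, i, i, seq_len(3) + (i - 1) * 3)
  }))
}

#' Random phage marker k-mer set
#'
#' Draws distinct k-mers used both to give planted cassettes their foreign
#' k-mer content and as the detector's marker lookup.
#'
#' @param n Number of k-mers.
#' @param k K-mer length.
#' @param seed Optional seed.
#' @return Character vector of distinct k-mers.
#' @export
random_marker_kmers <- function(n = 200, k = 12, seed = NULL) {
  with_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      m <- vapply(seq_len(n - length(out)), function(i)
        paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
        character(1))
      out <- unique(c(out, m))
    }
    out
  })
}

# iid random sequence with given GC fraction and strand skews
# gc_skew = (G-C)/(G+C), at_skew = (A-T)/(A+T)
rand_seq <- function(n, gc, gc_skew = 0, at_skew = 0) {
  p <- c(A = (1 - gc) * (1 + at_skew) / 2,
         C = gc * (1 - gc_skew) / 2,
         G = gc * (1 + gc_skew) / 2,
         T = (1 - gc) * (1 - at_skew) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# tile genes into [from, to]: lengths ~ N(mode, sd) clipped at min_len,
# spacings ~ N(space, space/3) clipped at 10
layout_genes <- function(from, to, mode, sd, min_len, space) {
  starts <- integer(0); ends <- integer(0)
  pos <- from
  repeat {
    len <- max(min_len, round(rnorm(1, mode, sd)))
    len <- len - len %% 3L  # keep codon-sized
    if (pos + len - 1 > to) break
    starts <- c(starts, pos); ends <- c(ends, pos + len - 1)
    pos <- pos + len + max(10, round(rnorm(1, space, space / 3)))
  }
  tibble(start = as.integer(starts), end = as.integer(ends))
}

#' Generate a host genome backbone
#'
#' An iid nucleotide backbone at a target GC with synthetic host gene
#' structure: gene lengths around 900 bp, modest intergenic spacing, and
#' strand assigned in alternating blocks, so that planted prophages (shorter
#' genes, long same-strand runs, foreign k-mers) contrast with it in every
#' feature the detector uses.
#'
#' @param length Backbone length in bp (>= 5000).
#' @param gc Target GC fraction, strictly inside (0, 1).
#' @param seed Optional seed.
#' @param accession Accession for the returned record.
#' @param gene_len_mode,gene_len_sd,min_gene_len,gene_spacing Host gene
#'   geometry (bp).
#' @return A one-contig [genome_record()].
#' @export
generate_backbone <- function(length, gc, seed = NULL, accession = "SYN_BACKBONE",
                              gene_len_mode = 900, gene_len_sd = 150,
                              min_gene_len = 300, gene_spacing = 120) {
  if (!is.numeric(length) || length < 5000)
    stop("backbone length must be at least 5,000 bp")
  if (gc <= 0 || gc >= 1) stop("gc must lie strictly inside (0, 1)")
  with_seed(seed, {
    seq <- rand_seq(length, gc)
    genes <- layout_genes(200, length - 200, gene_len_mode, gene_len_sd,
                          min_gene_len, gene_spacing)
    ng <- nrow(genes)
    # alternating strand blocks of ~5 genes
    strand <- character(ng)
    i <- 1; s <- "+"
    while (i <= ng) {
      b <- sample(3:8, 1)
      strand[i:min(ng, i + b - 1)] <- s
      s <- if (s == "+") "-" else "+"
      i <- i + b
    }
    cds <- mutate(genes, contig_id = "contig_1", strand = strand,
                  annotation = "hypothetical protein")
    genome_record(accession, contigs = c(contig_1 = seq),
                  cds = cds[, c("contig_id", "start", "end", "strand", "annotation")],
                  source = "isolate")
  })
}

#' Generate a prophage cassette
#'
#' A cassette carrying the compositional signals the detector keys on:
#' genes shorter than host genes (mode ~600 bp) and predominantly on one
#' strand; marker k-mers substituted into the sequence at a fixed rate
#' (default one per 150 bp); a skewed nucleotide composition so GC/AT skews
#' deviate from the host baseline; and an exact direct repeat of
#' `att_repeat_len` bp at both ends (the attL/attR pair formed at
#' integration).
#'
#' @param length Cassette length in bp.
#' @param marker_set Character vector of marker k-mers (all the same length).
#' @param seed Optional seed.
#' @param att_repeat_len att repeat length (bp).
#' @param gene_len_mode,gene_len_sd,min_gene_len,gene_spacing Cassette gene
#'   geometry (bp).
#' @param marker_rate Marker substitutions per bp (default 1/150).
#' @param gc,gc_skew,at_skew Cassette base composition.
#' @param phage_product_rate Fraction of genes annotated with phage product
#'   text.
#' @param strand Cassette strand carrying >= 90% of genes.
#' @return A list with elements `seq` (character), `cds` (cassette-relative
#'   coordinates), and `att` (left start, right start, length).
#' @export
generate_prophage <- function(length, marker_set, seed = NULL,
                              att_repeat_len = 12,
                              gene_len_mode = 600, gene_len_sd = 90,
                              min_gene_len = 200, gene_spacing = 50,
                              marker_rate = 1 / 150,
                              gc = 0.5, gc_skew = 0.25, at_skew = 0.15,
                              phage_product_rate = 0.3,
                              strand = "+") {
  if (length(marker_set) < 1) stop("marker_set must be non-empty")
  k <- nchar(marker_set[1])
  if (length < 5 * min_gene_len + 2 * att_repeat_len)
    stop("cassette of ", length, " bp cannot host 5 genes of >= ",
         min_gene_len, " bp")
  with_seed(seed, {
    seq <- rand_seq(length, gc, gc_skew = gc_skew, at_skew = at_skew)
    # substitute marker k-mers on a grid of non-overlapping slots
    n_mark <- max(1, floor(length * marker_rate))
    slots <- seq(att_repeat_len + 1, length - att_repeat_len - k, by = k)
    slots <- sort(sample(slots, min(n_mark, length(slots))))
    pieces <- substring(seq, c(1, slots + k), c(slots - 1, nchar(seq)))
    # cycle through a shuffled marker set so any reused marker's two copies
    # sit far apart: the boundary-refinement repeat search must find the
    # planted att pair, not an incidental marker-marker repeat
    marks <- rep(sample(marker_set), length.out = length(slots))
    seq <- paste0(paste0(pieces[seq_along(slots)], marks, collapse = ""),
                  pieces[length(pieces)])
    # exact direct repeat at both ends
    att <- substr(seq, 1, att_repeat_len)
    substr(seq, length - att_repeat_len + 1, length) <- att
    genes <- layout_genes(att_repeat_len + 5, length - att_repeat_len - 5,
                          gene_len_mode, gene_len_sd, min_gene_len, gene_spacing)
    ng <- nrow(genes)
    strands <- rep(strand, ng)
    n_off <- floor(ng * 0.1)
    if (n_off > 0)
      strands[ng - seq_len(n_off) + 1] <- if (strand == "+") "-" else "+"
    products <- ifelse(
      runif(ng) < phage_product_rate,
      sample(c("phage integrase", "phage major capsid protein",
               "phage terminase large subunit", "phage tail fiber protein",
               "phage portal protein", "putative prophage protein"),
             ng, replace = TRUE),
      "hypothetical protein")
    list(seq = seq,
         cds = mutate(genes, strand = strands, annotation = products),
         att = c(left = 1L, right = as.integer(length - att_repeat_len + 1),
                 length = as.integer(att_repeat_len)))
  })
}

# solve log-normal (meanlog, sdlog) from (mode, sd in bp)
lognormal_from_mode_sd <- function(mode, sd) {
  f <- function(s) mode * exp(1.5 * s^2) * sqrt(exp(s^2) - 1) - sd
  s <- uniroot(f, c(1e-4, 3))$root
  c(meanlog = log(mode) + s^2, sdlog = s)
}

draw_prophage_lengths <- function(spec, n) {
  cmp <- spec$prophage_len_components
  if (is.null(cmp))
    cmp <- tibble(weight = 1, mode = spec$prophage_len_mode,
                  sd = spec$prophage_len_sd)
  pars <- lapply(seq_len(nrow(cmp)),
                 function(i) lognormal_from_mode_sd(cmp$mode[i], cmp$sd[i]))
  comp <- sample.int(nrow(cmp), n, replace = TRUE, prob = cmp$weight)
  len <- vapply(comp, function(ci)
    rlnorm(1, pars[[ci]]["meanlog"], pars[[ci]]["sdlog"]), numeric(1))
  tibble(component = comp,
         length = as.integer(pmax(spec$min_cassette_len, round(len))))
}

#' Plant prophage cassettes into a genome
#'
#' Inserts prophage cassettes into intergenic gaps of a host genome until
#' the planted total reaches the target genomic density (planted bp per bp
#' of host backbone, i.e. the genome length *excluding* the prophages).
#' Cassette lengths are drawn from the spec's log-normal (mixture)
#' distribution; the cassette count is chosen so the planted total lands as
#' close to the target as the draws allow, and the final cassette is
#' resized if needed to keep the achieved density within +/-20% (relative)
#' of the target. Insertions are kept at least 2,500 bp away from contig
#' edges and never overlap.
#'
#' @param genome A [genome_record()] with sequence (a backbone from
#'   [generate_backbone()]).
#' @param spec A [synthetic_spec()].
#' @param seed Optional seed.
#' @param marker_set Marker k-mers for the cassettes (defaults to a set
#'   drawn from the ambient RNG stream).
#' @return A list: `genome` (with cassettes inserted and CDS shifted) and
#'   `truth` (one row per planted prophage: `accession`, `contig_id`,
#'   `start`, `end`, `length`, `component`, `retained`).
#' @export
plant_prophages <- function(genome, spec, seed = NULL, marker_set = NULL) {
  stopifnot(inherits(genome, "genome_record"), inherits(spec, "synthetic_spec"))
  empty_truth <- tibble(accession = character(), contig_id = character(),
                        start = integer(), end = integer(), length = integer(),
                        component = integer(), retained = logical())
  if (spec$target_density == 0)
    return(list(genome = genome, truth = empty_truth))
  with_seed(seed, {
    if (is.null(marker_set))
      marker_set <- random_marker_kmers(spec$marker_kmer_count, spec$kmer_k)
    backbone_bp <- genome_length(genome)
    target_bp <- spec$target_density * backbone_bp
    band <- 0.2

    # sequential draws, then keep whichever of k-1/k cassettes lands closer
    draws <- draw_prophage_lengths(spec, 64)
    csum <- cumsum(draws$length)
    k <- match(TRUE, csum >= target_bp)
    if (is.na(k)) { # extremely small target relative to cassette sizes
      draws <- bind_rows(draws, draw_prophage_lengths(spec, 512))
      csum <- cumsum(draws$length)
      k <- match(TRUE, csum >= target_bp, nomatch = nrow(draws))
    }
    if (k > 1 && abs(csum[k - 1] - target_bp) < abs(csum[k] - target_bp))
      k <- k - 1
    cassettes <- draws[seq_len(k), ]
    total <- sum(cassettes$length)
    lo <- (1 - band) * target_bp; hi <- (1 + band) * target_bp
    if (total < lo || total > hi) {
      adjust <- round(min(hi, max(lo, target_bp))) - (total - cassettes$length[k])
      cassettes$length[k] <- as.integer(max(spec$min_cassette_len, adjust))
    }

    # candidate insertion gaps (intergenic, >= 2,500 bp from contig edges)
    gaps <- genome$cds |>
      group_by(.data$contig_id) |>
      dplyr::reframe({
        len <- genome$contig_lengths$length[
          match(.data$contig_id[1], genome$contig_lengths$contig_id)]
        bounds <- sort(c(0L, .data$end, len))
        starts <- c(0L, .data$end)
        ends <- c(.data$start - 1L, len)
        tibble(gap_lo = starts, gap_hi = ends)
      }) |>
      ungroup() |>
      filter(.data$gap_hi >= .data$gap_lo,
             .data$gap_hi >= 2500,
             .data$gap_lo <= vapply(.data$contig_id, function(cid)
               genome$contig_lengths$length[
                 match(cid, genome$contig_lengths$contig_id)] - 2500,
               numeric(1)))
    gaps <- mutate(gaps,
                   gap_lo = pmax(.data$gap_lo, 2500),
                   gap_hi = pmin(.data$gap_hi, vapply(.data$contig_id, function(cid)
                     genome$contig_lengths$length[
                       match(cid, genome$contig_lengths$contig_id)] - 2500,
                     numeric(1)))) |>
      filter(.data$gap_hi >= .data$gap_lo)
    if (nrow(gaps) < nrow(cassettes))
      stop("target density ", spec$target_density, " is infeasible for '",
           genome$accession, "': only ", nrow(gaps),
           " usable insertion gaps for ", nrow(cassettes), " cassettes ",
           "(genome too small or too gene-dense)")
    chosen <- gaps[sample.int(nrow(gaps), nrow(cassettes)), ]
    chosen$point <- floor(runif(nrow(chosen), chosen$gap_lo, chosen$gap_hi + 1))

    # build cassettes and insert, contig by contig
    truth <- empty_truth
    contigs <- as.character(genome$contigs)
    cds_all <- genome$cds
    for (cid in unique(chosen$contig_id)) {
      rows <- which(chosen$contig_id == cid)
      rows <- rows[order(chosen$point[rows])]
      pts <- chosen$point[rows]
      lens <- cassettes$length[rows]
      comps <- cassettes$component[rows]
      cass <- lapply(seq_along(rows), function(i)
        generate_prophage(lens[i], marker_set,
                          att_repeat_len = spec$att_repeat_len,
                          phage_product_rate = spec$phage_product_rate,
                          strand = sample(c("+", "-"), 1)))
      seq0 <- contigs[[cid]]
      pieces <- substring(seq0, c(1, pts + 1), c(pts, nchar(seq0)))
      new_seq <- paste0(paste0(pieces[seq_along(pts)],
                               vapply(cass, `[[`, character(1), "seq"),
                               collapse = ""),
                        pieces[length(pieces)])
      offset <- c(0, cumsum(lens))
      starts <- pts + offset[seq_along(pts)] + 1L
      ends <- starts + lens - 1L
      # make the planted att pair the *maximal* repeat: force the backbone
      # bases flanking the cassette to mismatch the cassette bases adjacent
      # to the inner repeat copies, so seed-and-extend stops at 12 bp
      bases <- c("A", "C", "G", "T")
      for (i in seq_along(starts)) {
        s <- starts[i]; e <- ends[i]; att <- spec$att_repeat_len
        inner_l <- substr(new_seq, e - att, e - att)      # base before attR
        inner_r <- substr(new_seq, s + att, s + att)      # base after attL
        if (substr(new_seq, s - 1, s - 1) == inner_l)
          substr(new_seq, s - 1, s - 1) <- setdiff(bases, inner_l)[1]
        if (substr(new_seq, e + 1, e + 1) == inner_r)
          substr(new_seq, e + 1, e + 1) <- setdiff(bases, inner_r)[1]
      }
      truth <- bind_rows(truth, tibble(
        accession = genome$accession, contig_id = cid,
        start = as.integer(starts), end = as.integer(ends),
        length = as.integer(lens), component = as.integer(comps),
        retained = TRUE))
      # shift host CDS past each insertion point
      idx <- cds_all$contig_id == cid
      shift <- vapply(cds_all$start[idx], function(s)
        offset[findInterval(s - 1, pts) + 1], numeric(1))
      cds_all$start[idx] <- as.integer(cds_all$start[idx] + shift)
      cds_all$end[idx] <- as.integer(cds_all$end[idx] + shift)
      # cassette CDS in genome coordinates
      for (i in seq_along(rows)) {
        cc <- cass[[i]]$cds
        cds_all <- bind_rows(cds_all, tibble(
          contig_id = cid,
          start = as.integer(cc$start + starts[i] - 1L),
          end = as.integer(cc$end + starts[i] - 1L),
          strand = cc$strand, annotation = cc$annotation,
          length = as.integer(cc$end - cc$start + 1L)))
      }
      contigs[[cid]] <- new_seq
    }
    out <- genome_record(genome$accession, contigs = contigs,
                         cds = arrange(cds_all, .data$contig_id, .data$start),
                         source = genome$source)
    list(genome = out, truth = arrange(truth, .data$contig_id, .data$start))
  })
}

#' Degrade a genome the way MAG assembly loses prophages
#'
#' Metagenome-assembled genomes under-represent prophages because prophage
#' reads bin poorly with the host backbone. This is emulated by removing
#' each planted prophage with probability `loss_prob` and splitting the
#' contig at the excision point, so the expected retained prophage density
#' is `(1 - loss_prob)` times the original.
#'
#' @param genome A [genome_record()].
#' @param truth Truth rows for this genome (from [plant_prophages()]).
#' @param loss_prob Per-prophage loss probability in `[0, 1]`.
#' @param seed Optional seed.
#' @return A list: `genome` (contigs split at excisions, source set to
#'   `"MAG"`) and `truth` (lost rows flagged `retained = FALSE`, kept rows
#'   remapped to the new contigs).
#' @export
mag_degrade <- function(genome, truth, loss_prob, seed = NULL) {
  stopifnot(inherits(genome, "genome_record"))
  if (loss_prob < 0 || loss_prob > 1) stop("loss_prob must be in [0, 1]")
  truth <- as_tibble(truth)
  mine <- truth$accession == genome$accession & truth$retained
  with_seed(seed, {
    lost <- mine & runif(nrow(truth)) < loss_prob
    if (!any(mine) || loss_prob == 0 || !any(lost)) {
      genome$source <- "MAG"
      return(list(genome = genome, truth = truth))
    }
    contigs_out <- list(); cds_out <- list(); truth_out <- truth[!mine, ]
    has_seq <- !is.null(genome$contigs)
    lengths_out <- list()
    for (cid in genome$contig_lengths$contig_id) {
      clen <- genome$contig_lengths$length[
        match(cid, genome$contig_lengths$contig_id)]
      cut <- truth[lost & truth$contig_id == cid, ]
      keep <- truth[mine & !lost & truth$contig_id == cid, ]
      if (nrow(cut) == 0) {
        if (has_seq) contigs_out[[cid]] <- as.character(genome$contigs[[cid]])
        lengths_out[[cid]] <- clen
        if (nrow(keep)) truth_out <- bind_rows(truth_out, keep)
        if (has_seq) {
          cds_out[[cid]] <- genome$cds[genome$cds$contig_id == cid, ]
        }
        next
      }
      cut <- arrange(cut, .data$start)
      piece_lo <- c(1L, cut$end + 1L)
      piece_hi <- c(cut$start - 1L, clen)
      for (p in seq_along(piece_lo)) {
        if (piece_hi[p] < piece_lo[p]) next
        pid <- paste0(cid, "_p", p)
        off <- piece_lo[p] - 1L
        plen <- piece_hi[p] - piece_lo[p] + 1L
        if (has_seq)
          contigs_out[[pid]] <- substr(as.character(genome$contigs[[cid]]),
                                       piece_lo[p], piece_hi[p])
        lengths_out[[pid]] <- plen
        if (has_seq) {
          cc <- genome$cds[genome$cds$contig_id == cid &
                             genome$cds$start >= piece_lo[p] &
                             genome$cds$end <= piece_hi[p], ]
          if (nrow(cc)) {
            cc$contig_id <- pid
            cc$start <- cc$start - off
            cc$end <- cc$end - off
            cds_out[[pid]] <- cc
          }
        }
        kk <- keep[keep$start >= piece_lo[p] & keep$end <= piece_hi[p], ]
        if (nrow(kk)) {
          kk$contig_id <- pid
          kk$start <- as.integer(kk$start - off)
          kk$end <- as.integer(kk$end - off)
          truth_out <- bind_rows(truth_out, kk)
        }
      }
      dropped <- cut
      dropped$retained <- FALSE
      truth_out <- bind_rows(truth_out, dropped)
    }
    g <- genome_record(
      genome$accession,
      contigs = if (has_seq) unlist(contigs_out) else NULL,
      cds = if (has_seq) bind_rows(cds_out) else NULL,
      source = "MAG",
      contig_lengths = if (!has_seq)
        tibble(contig_id = names(lengths_out),
               length = unlist(lengths_out)) else NULL)
    list(genome = g, truth = truth_out)
  })
}

#' Generate a synthetic lysogen cohort
#'
#' Draws `n_genomes` host genomes (log-normal lengths, or uniform over
#' `genome_len_range`), plants prophages into the lysogenic fraction at
#' the target density, degrades the MAG fraction with [mag_degrade()],
#' and emits metadata (isolation date in mixed formats, country, GTDB-style
#' lineage, MAG flag) plus the planted ground truth. All randomness flows
#' from `spec$seed`: equal specs give bit-identical cohorts.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory; when given, one GenBank file per
#'   genome plus `metadata.tsv` and `truth.tsv` are written there.
#' @param sequences When `FALSE`, genomes are generated at the coordinate
#'   level only (lengths and planted regions, no nucleotide sequence or
#'   CDS layout) -- orders of magnitude faster, and sufficient for the
#'   density/length statistics, but not for detection.
#' @return A `prophage_cohort`: list with `genomes` (list of
#'   [genome_record()]), `metadata` (tibble), `truth` (tibble),
#'   `genome_meta` (per-genome true density and lysogen flag),
#'   `marker_set`, and `spec`.
#' @export
generate_cohort <- function(spec, dir = NULL, sequences = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!length(spec$country_pool)) stop("country_pool is empty")
  if (!length(spec$taxon_pool)) stop("taxon_pool is empty")
  with_seed(spec$seed, {
    n <- spec$n_genomes
    marker_set <- random_marker_kmers(spec$marker_kmer_count, spec$kmer_k)
    if (!is.null(spec$genome_len_range)) {
      glen <- round(runif(n, spec$genome_len_range[1], spec$genome_len_range[2]))
    } else {
      lp <- lognormal_from_mode_sd(spec$genome_len_mode, spec$genome_len_spread)
      glen <- round(rlnorm(n, lp["meanlog"], lp["sdlog"]))
    }
    glen <- pmax(glen, 200000)
    lysogen <- runif(n) < spec$lysogen_fraction
    is_mag <- runif(n) < spec$mag_fraction
    year <- runif(n, spec$year_range[1], spec$year_range[2] + 1)
    country <- sample(spec$country_pool, n, replace = TRUE)
    taxon <- sample(spec$taxon_pool, n, replace = TRUE)
    acc <- sprintf("SYN_%05d.1", seq_len(n))

    date_str <- vapply(year, function(y) {
      d <- as.Date(sprintf("%d-01-01", floor(y))) +
        round((y - floor(y)) * 364)
      style <- sample(c("iso", "ym", "y", "none"), 1,
                      prob = c(0.8, 0.1, 0.07, 0.03))
      switch(style,
             iso = format(d, "%Y-%m-%d"),
             ym = format(d, "%Y-%m"),
             y = format(d, "%Y"),
             none = "not collected")
    }, character(1))

    genomes <- vector("list", n)
    truth_all <- list()
    for (i in seq_len(n)) {
      gseed <- sample.int(.Machine$integer.max - 1, 1)
      if (sequences) {
        g <- generate_backbone(glen[i], spec$backbone_gc, seed = gseed,
                               accession = acc[i])
        if (lysogen[i]) {
          pl <- plant_prophages(g, spec, seed = gseed + 1L,
                                marker_set = marker_set)
          g <- pl$genome; tr <- pl$truth
        } else tr <- NULL
      } else {
        g <- genome_record(acc[i],
                           contig_lengths = tibble(contig_id = "contig_1",
                                                   length = glen[i]),
                           source = "isolate")
        tr <- if (lysogen[i])
          plant_coordinates(acc[i], glen[i], spec, seed = gseed + 1L) else NULL
      }
      if (is_mag[i]) {
        md <- mag_degrade(g, tr %||% tibble(accession = character(),
                                            contig_id = character(),
                                            start = integer(), end = integer(),
                                            length = integer(),
                                            component = integer(),
                                            retained = logical()),
                          spec$mag_loss_prob, seed = gseed + 2L)
        g <- md$genome; tr <- md$truth
      }
      genomes[[i]] <- g
      if (!is.null(tr) && nrow(tr)) truth_all[[length(truth_all) + 1L]] <- tr
    }
    truth <- if (length(truth_all)) bind_rows(truth_all) else
      tibble(accession = character(), contig_id = character(),
             start = integer(), end = integer(), length = integer(),
             component = integer(), retained = logical())

    planted_bp <- vapply(acc, function(a)
      sum(truth$length[truth$accession == a & truth$retained]), numeric(1))
    genome_bp <- vapply(genomes, genome_length, numeric(1))
    genome_meta <- tibble(
      accession = acc,
      genome_bp = unname(genome_bp - planted_bp),   # host bp, prophages excluded
      prophage_bp = unname(planted_bp),
      true_density = .data$prophage_bp / .data$genome_bp,
      is_lysogen = .data$prophage_bp > 0,
      planted = lysogen)

    metadata <- tibble(
      assembly_accession = acc,
      isolation_date = date_str,
      country = country,
      gtdb_lineage = taxon,
      is_mag = is_mag)

    cohort <- structure(
      list(genomes = genomes, metadata = metadata, truth = truth,
           genome_meta = genome_meta, marker_set = marker_set, spec = spec),
      class = "prophage_cohort")
    if (!is.null(dir)) write_cohort(cohort, dir)
    cohort
  })
}

# coordinate-only planting used by generate_cohort(sequences = FALSE):
# identical length/count logic to plant_prophages, positions drawn
# directly on the backbone coordinate line
plant_coordinates <- function(accession, backbone_bp, spec, seed = NULL) {
  with_seed(seed, {
    target_bp <- spec$target_density * backbone_bp
    if (target_bp == 0) return(NULL)
    band <- 0.2
    draws <- draw_prophage_lengths(spec, 64)
    csum <- cumsum(draws$length)
    k <- match(TRUE, csum >= target_bp, nomatch = nrow(draws))
    if (k > 1 && abs(csum[k - 1] - target_bp) < abs(csum[k] - target_bp))
      k <- k - 1
    cassettes <- draws[seq_len(k), ]
    total <- sum(cassettes$length)
    lo <- (1 - band) * target_bp; hi <- (1 + band) * target_bp
    if (total < lo || total > hi) {
      adjust <- round(min(hi, max(lo, target_bp))) -
        (total - cassettes$length[k])
      cassettes$length[k] <- as.integer(max(spec$min_cassette_len, adjust))
    }
    if (backbone_bp < 2 * 2500 + 10)
      stop("target density infeasible: backbone of ", backbone_bp,
           " bp leaves no room 2,500 bp clear of contig edges")
    pts <- sort(floor(runif(nrow(cassettes), 2500, backbone_bp - 2500)))
    offset <- c(0, cumsum(cassettes$length))
    starts <- pts + offset[seq_len(nrow(cassettes))] + 1L
    tibble(accession = accession, contig_id = "contig_1",
           start = as.integer(starts),
           end = as.integer(starts + cassettes$length - 1L),
           length = as.integer(cassettes$length),
           component = as.integer(cassettes$component),
           retained = TRUE)
  })
}

#' Write a cohort to disk
#'
#' @param cohort A `prophage_cohort` with sequences.
#' @param dir Output directory (created if needed): one `.gbff` per
#'   genome, `metadata.tsv`, `truth.tsv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "prophage_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in cohort$genomes) {
    if (is.null(g$contigs)) next
    write_genbank(g, file.path(dir, paste0(g$accession, ".gbff")))
  }
  write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$truth, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.prophage_cohort <- function(x, ...) {
  cat("<prophage_cohort> ", length(x$genomes), " genomes, ",
      sum(x$genome_meta$is_lysogen), " lysogens, ",
      sum(x$truth$retained), " retained planted prophages\n", sep = "")
  invisible(x)
}
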