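#' Call open reading frames on a naked sequence
#'
#' FASTA-input fallback for records without CDS annotation: maximal
#' start-to-stop ORFs (first in-frame ATG after the previous in-frame stop,
#' through the stop codon) on all six frames, at least `min_orf_len` bp.
#'
#' @param seq Contig sequence (character scalar over `A`, `C`, `G`, `T`,
#'   `N`).
#' @param min_orf_len Minimum ORF length in bp, stop codon included.
#' @param contig_id Contig label for the output rows.
#' @return Tibble of ORFs (`contig_id`, `start`, `end`, `strand`,
#'   `length`, `annotation`), sorted by `start`; 1-based inclusive
#'   coordinates on the forward strand.
#' @export
call_orfs <- function(seq, min_orf_len = 90, contig_id = "contig_1") {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- tibble(contig_id = character(), start = integer(), end = integer(),
                  strand = character(), length = integer(),
                  annotation = character())
  if (n < min_orf_len) return(empty)
  scan_strand <- function(s, strand) {
    m <- nchar(s)
    codons_at <- function(frame) {
      pos <- seq(frame, m - 2, by = 3)
      cod <- substring(s, pos, pos + 2)
      list(pos = pos, cod = cod)
    }
    out <- list()
    for (frame in 1:3) {
      if (m - 2 < frame) next
      cf <- codons_at(frame)
      is_stop <- cf$cod %in% c("TAA", "TAG", "TGA")
      is_atg <- cf$cod == "ATG"
      # segment index between stops
      seg <- cumsum(c(FALSE, head(is_stop, -1)))
      for (sg in split(seq_along(cf$pos), seg)) {
        stops <- sg[is_stop[sg]]
        if (!length(stops)) next       # ORF must end at a stop
        stop_i <- stops[1]
        starts <- sg[is_atg[sg] & sg < stop_i]
        if (!length(starts)) next
        a <- cf$pos[starts[1]]
        b <- cf$pos[stop_i] + 2
        if (b - a + 1 >= min_orf_len)
          out[[length(out) + 1L]] <- c(a, b)
      }
    }
    if (!length(out)) return(NULL)
    mat <- do.call(rbind, out)
    if (strand == "+") {
      tibble(start = mat[, 1], end = mat[, 2], strand = "+")
    } else {
      tibble(start = m - mat[, 2] + 1L, end = m - mat[, 1] + 1L, strand = "-")
    }
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  res <- bind_rows(scan_strand(seq, "+"), scan_strand(rc, "-"))
  if (is.null(res) || !nrow(res)) return(empty)
  res |>
    mutate(contig_id = contig_id, length = as.integer(.data$end - .data$start + 1),
           start = as.integer(.data$start), end = as.integer(.data$end),
           annotation = "predicted ORF") |>
    select("contig_id", "start", "end", "strand", "length", "annotation") |>
    arrange(.data$start, .data$end)
}

#' Genome-wide GC and AT skew baseline
#'
#' @param genome A [genome_record()] with sequence.
#' @return Named numeric vector `c(gc_skew, at_skew)` over all contigs,
#'   where GC skew is `(G - C) / (G + C)` and AT skew `(A - T) / (A + T)`
#'   (0 when the denominator is 0).
#' @export
genome_baseline_skews <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  if (is.null(genome$contigs)) stop("record carries no sequence")
  f <- colSums(Biostrings::letterFrequency(genome$contigs, c("A", "C", "G", "T")))
  skew <- function(a, b) if (a + b == 0) 0 else (a - b) / (a + b)
  c(gc_skew = skew(f[["G"]], f[["C"]]), at_skew = skew(f[["A"]], f[["T"]]))
}

#' Per-ORF GC/AT skew deviations from the genome baseline
#'
#' @param seq Contig sequence (character scalar).
#' @param orfs Tibble with `start`, `end` columns (1-based inclusive).
#' @param genome_baseline Named vector `c(gc_skew, at_skew)` from
#'   [genome_baseline_skews()].
#' @return `orfs` with `gc_skew_dev` and `at_skew_dev` columns appended:
#'   the ORF-span skew minus the baseline.
#' @export
compute_skews <- function(seq, orfs, genome_baseline = c(gc_skew = 0, at_skew = 0)) {
  orfs <- as_tibble(orfs)
  if (!nrow(orfs)) {
    orfs$gc_skew_dev <- numeric(0); orfs$at_skew_dev <- numeric(0)
    return(orfs)
  }
  v <- Biostrings::Views(Biostrings::DNAString(toupper(seq)),
                         start = orfs$start, end = orfs$end)
  f <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
  gden <- f[, "G"] + f[, "C"]
  aden <- f[, "A"] + f[, "T"]
  gsk <- ifelse(gden == 0, 0, (f[, "G"] - f[, "C"]) / gden)
  ask <- ifelse(aden == 0, 0, (f[, "A"] - f[, "T"]) / aden)
  orfs$gc_skew_dev <- unname(gsk) - unname(genome_baseline["gc_skew"])
  orfs$at_skew_dev <- unname(ask) - unname(genome_baseline["at_skew"])
  orfs
}

# logical vector over the n-k+1 k-mer start positions of seq: is the k-mer
# a member of marker_set?  chunked to bound peak memory on long contigs.
marker_hit_positions <- function(seq, marker_set, k) {
  n <- nchar(seq)
  if (n < k) return(logical(0))
  npos <- n - k + 1
  hits <- logical(npos)
  chunk <- 5e5
  at <- 1
  while (at <= npos) {
    hi <- min(npos, at + chunk - 1)
    w <- substring(seq, at:hi, (at:hi) + k - 1)
    hits[at:hi] <- w %in% marker_set
    at <- hi + 1
  }
  hits
}

#' Phage marker k-mer score of a sequence
#'
#' The fraction of k-mer window positions whose k-mer belongs to the phage
#' marker set: `hits / (|seq| - k + 1)`, in `[0, 1]`. Sequences shorter
#' than `k` score 0 with a warning.
#'
#' @param seq Character scalar (an ORF or region sequence).
#' @param marker_set Character vector of marker k-mers.
#' @param k K-mer length (default 12; must match the marker set).
#' @return Scalar score in `[0, 1]`.
#' @export
kmer_phage_score <- function(seq, marker_set, k = 12) {
  seq <- toupper(seq)
  if (nchar(seq) < k) {
    warning("sequence shorter than k = ", k, "; score 0")
    return(0)
  }
  h <- marker_hit_positions(seq, marker_set, k)
  sum(h) / length(h)
}

# per-ORF marker window counts/scores from a precomputed hit vector
orf_marker_stats <- function(hits, orfs, k) {
  cs <- cumsum(c(0L, hits))
  npos <- length(hits)
  lo <- pmin(pmax(orfs$start, 1L), npos + 1L)
  hi <- pmax(pmin(orfs$end - k + 1L, npos), lo - 1L)
  cnt <- cs[hi + 1L] - cs[lo]
  nwin <- pmax(hi - lo + 1L, 0L)
  tibble(marker_windows = as.integer(cnt),
         phage_kmer_score = ifelse(nwin > 0, cnt / nwin, 0))
}

#' Sliding-window ORF metrics
#'
#' For each ORF, statistics over the up-to-`window_size`-ORF window centred
#' on it (truncated at contig ends): the median ORF length, the longest
#' same-strand run divided by the window length, and the window means of
#' the marker k-mer score and the GC/AT skew deviations. These five
#' features feed the classifier.
#'
#' @param orfs Tibble sorted by `start` within one contig, carrying
#'   `length`, `strand`, `phage_kmer_score`, `gc_skew_dev`, `at_skew_dev`.
#' @param window_size Window size in ORFs (default 30).
#' @return `orfs` with feature columns `median_orf_len`,
#'   `same_strand_run`, and windowed `phage_kmer_score`, `gc_skew_dev`,
#'   `at_skew_dev` (the raw per-ORF values are kept with a `_raw` suffix).
#' @export
window_metrics <- function(orfs, window_size = 30) {
  orfs <- as_tibble(orfs)
  n <- nrow(orfs)
  if (!n) {
    for (cl in c("median_orf_len", "same_strand_run")) orfs[[cl]] <- numeric(0)
    return(orfs)
  }
  if (is.unsorted(orfs$start)) stop("orfs must be sorted by start")
  half_lo <- floor(window_size / 2)
  lo <- pmax(1L, seq_len(n) - half_lo)
  hi <- pmin(n, lo + window_size - 1L)
  lo <- pmax(1L, hi - window_size + 1L)
  med <- numeric(n); run <- numeric(n)
  ksc <- numeric(n); gcd <- numeric(n); atd <- numeric(n)
  len <- orfs$length; strand <- orfs$strand
  sc <- orfs$phage_kmer_score; gd <- orfs$gc_skew_dev; ad <- orfs$at_skew_dev
  for (i in seq_len(n)) {
    w <- lo[i]:hi[i]
    med[i] <- median(len[w])
    r <- rle(strand[w])
    run[i] <- max(r$lengths) / length(w)
    ksc[i] <- mean(sc[w])
    gcd[i] <- mean(gd[w])
    atd[i] <- mean(ad[w])
  }
  orfs$phage_kmer_score_raw <- orfs$phage_kmer_score
  orfs$gc_skew_dev_raw <- orfs$gc_skew_dev
  orfs$at_skew_dev_raw <- orfs$at_skew_dev
  orfs$median_orf_len <- med
  orfs$same_strand_run <- run
  orfs$phage_kmer_score <- ksc
  orfs$gc_skew_dev <- gcd
  orfs$at_skew_dev <- atd
  orfs
}

classifier_features <- c("median_orf_len", "same_strand_run",
                         "phage_kmer_score", "gc_skew_dev", "at_skew_dev")

#' Train the prophage ORF classifier
#'
#' A random forest (default 500 trees) over the five window features,
#' labelled by simulator ground truth (ORFs inside planted prophages are
#' `phage`, the rest `host`).
#'
#' @param metrics Tibble of feature rows (see [window_metrics()]).
#' @param labels Factor or character vector (`"phage"`/`"host"`), one per
#'   row.
#' @param n_trees Number of trees (default 500).
#' @param seed Optional seed for the forest.
#' @param threshold Phage-probability decision threshold (default 0.5).
#' @return A `prophage_classifier` object.
#' @export
train_classifier <- function(metrics, labels, n_trees = 500, seed = NULL,
                             threshold = 0.5) {
  metrics <- as_tibble(metrics)
  miss <- setdiff(classifier_features, names(metrics))
  if (length(miss))
    stop("metrics are missing feature columns: ", paste(miss, collapse = ", "))
  labels <- factor(as.character(labels), levels = c("host", "phage"))
  if (anyNA(labels)) stop("labels must be 'host' or 'phage'")
  if (nrow(metrics) < 100)
    stop("need at least 100 labelled ORFs to train (got ", nrow(metrics), ")")
  if (length(unique(labels)) < 2)
    stop("training data must contain both classes")
  x <- as.data.frame(metrics[, classifier_features])
  fit <- with_seed(seed, randomForest::randomForest(
    x = x, y = labels, ntree = n_trees, importance = TRUE))
  structure(list(model = fit, features = classifier_features,
                 threshold = threshold, n_trees = n_trees, seed = seed,
                 n_train = nrow(x),
                 oob_accuracy = 1 - unname(fit$err.rate[n_trees, "OOB"])),
            class = "prophage_classifier")
}

#' @export
print.prophage_classifier <- function(x, ...) {
  cat("<prophage_classifier> ", x$n_trees, " trees, ", x$n_train,
      " training ORFs, OOB accuracy ", round(x$oob_accuracy, 4),
      ", threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Predict phage probability for ORF metric rows
#'
#' @param object A `prophage_classifier`.
#' @param newdata Tibble carrying the five feature columns.
#' @param type `"prob"` for the phage-class probability, `"class"` for the
#'   thresholded label.
#' @param ... Unused.
#' @return Numeric probabilities or a factor, one per row.
#' @export
predict.prophage_classifier <- function(object, newdata,
                                        type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as_tibble(newdata)
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    stop("newdata does not match the classifier feature schema; missing: ",
         paste(miss, collapse = ", "))
  p <- predict(object$model,
               newdata = as.data.frame(newdata[, object$features]),
               type = "prob")[, "phage"]
  if (type == "prob") unname(p)
  else factor(ifelse(p >= object$threshold, "phage", "host"),
              levels = c("host", "phage"))
}

#' Assemble per-ORF predictions into candidate prophage regions
#'
#' Maximal runs of phage-predicted ORFs, tolerating up to `gap_tolerance`
#' consecutive host-predicted ORFs inside a run (prophages carry non-viral
#' cargo). Runs with fewer than `min_genes` phage-predicted ORFs are
#' emitted with status `discarded` (reason `too_few_genes`); all others are
#' `pending` until verification. The region span runs from the first to
#' the last phage-predicted ORF of the run.
#'
#' @param predictions Tibble with `contig_id`, `start`, `end` and logical
#'   `phage` columns, ordered by position within each contig.
#' @param min_genes Minimum phage-predicted ORFs per kept region (default
#'   5).
#' @param gap_tolerance Host-predicted ORFs tolerated inside a run
#'   (default 2).
#' @return Tibble of regions: `contig_id`, `start`, `end`, `n_genes`,
#'   `first_orf`, `last_orf`, `status`, `discard_reason`.
#' @export
assemble_regions <- function(predictions, min_genes = 5, gap_tolerance = 2) {
  predictions <- as_tibble(predictions)
  out <- list()
  for (cid in unique(predictions$contig_id)) {
    p <- predictions[predictions$contig_id == cid, ]
    ph <- which(p$phage)
    if (!length(ph)) next
    brk <- which(diff(ph) > gap_tolerance + 1)
    grp_start <- c(1, brk + 1)
    grp_end <- c(brk, length(ph))
    for (g in seq_along(grp_start)) {
      ix <- ph[grp_start[g]:grp_end[g]]
      ng <- length(ix)
      out[[length(out) + 1L]] <- tibble(
        contig_id = cid,
        start = p$start[ix[1]], end = p$end[ix[ng]],
        n_genes = ng, first_orf = ix[1], last_orf = ix[ng],
        status = if (ng >= min_genes) "pending" else "discarded",
        discard_reason = if (ng >= min_genes) NA_character_ else "too_few_genes")
    }
  }
  if (!length(out))
    return(tibble(contig_id = character(), start = integer(), end = integer(),
                  n_genes = integer(), first_orf = integer(),
                  last_orf = integer(), status = character(),
                  discard_reason = character()))
  bind_rows(out)
}

# longest exact direct repeat with one copy in each window; seed-and-extend
find_direct_repeat <- function(seq, lwin, rwin, min_repeat_len) {
  lw <- substr(seq, lwin[1], lwin[2])
  rw <- substr(seq, rwin[1], rwin[2])
  k <- min_repeat_len
  if (nchar(lw) < k || nchar(rw) < k) return(NULL)
  lk <- substring(lw, 1:(nchar(lw) - k + 1), k:nchar(lw))
  rk <- substring(rw, 1:(nchar(rw) - k + 1), k:nchar(rw))
  common <- intersect(lk, rk)
  common <- setdiff(common, common[grepl("N", common)])
  if (!length(common)) return(NULL)
  cand <- list()
  for (km in common) {
    lp <- which(lk == km) + lwin[1] - 1L
    rp <- which(rk == km) + rwin[1] - 1L
    pairs <- expand.grid(al = lp, ar = rp)
    pairs <- pairs[pairs$ar >= pairs$al + k, , drop = FALSE]
    if (nrow(pairs) > 500) pairs <- pairs[seq_len(500), , drop = FALSE]
    for (i in seq_len(nrow(pairs))) {
      al <- pairs$al[i]; ar <- pairs$ar[i]; len <- k
      # extend left
      while (al > lwin[1] && ar > rwin[1] && ar - 1 >= al - 1 + len + 1 &&
             substr(seq, al - 1, al - 1) == substr(seq, ar - 1, ar - 1)) {
        al <- al - 1L; ar <- ar - 1L; len <- len + 1L
      }
      # extend right
      while (al + len <= lwin[2] && ar + len <= rwin[2] &&
             ar >= al + len + 1 &&
             substr(seq, al + len, al + len) == substr(seq, ar + len, ar + len)) {
        len <- len + 1L
      }
      cand[[length(cand) + 1L]] <- c(al = al, ar = ar, len = len)
    }
  }
  if (!length(cand)) return(NULL)
  m <- unique(do.call(rbind, cand))
  as_tibble(as.data.frame(m))
}

#' Refine region boundaries with flanking direct repeats
#'
#' Searches `extra_dna` bp on either side of each boundary for the longest
#' exact direct-repeat pair of at least `min_repeat_len` bp with one copy
#' in the left window and one in the right (the att site formed at
#' integration). When found, the region snaps to the outer edges of the
#' two copies; ties on length are broken by the smallest total boundary
#' displacement. Without a qualifying repeat the region is unchanged.
#'
#' @param region One-row region tibble (from [assemble_regions()]).
#' @param seq The contig sequence.
#' @param extra_dna Window half-width in bp (default 2000).
#' @param min_repeat_len Minimum repeat length in bp (default 10).
#' @return The region row with `start`/`end` possibly snapped and
#'   `att_left`, `att_right`, `att_len` filled in.
#' @export
refine_boundaries <- function(region, seq, extra_dna = 2000,
                              min_repeat_len = 10) {
  n <- nchar(seq)
  region$att_left <- NA_integer_
  region$att_right <- NA_integer_
  region$att_len <- NA_integer_
  lwin <- c(max(1L, region$start - extra_dna),
            min(n, region$start + extra_dna - 1L))
  rwin <- c(max(1L, region$end - extra_dna + 1L),
            min(n, region$end + extra_dna))
  if (rwin[1] <= lwin[2]) { # windows overlap for short regions; split midway
    mid <- (region$start + region$end) %/% 2
    lwin[2] <- min(lwin[2], mid)
    rwin[1] <- max(rwin[1], mid + 1L)
  }
  rep_ <- find_direct_repeat(seq, lwin, rwin, min_repeat_len)
  if (is.null(rep_) || !nrow(rep_)) return(region)
  rep_$disp <- abs(rep_$al - region$start) +
    abs((rep_$ar + rep_$len - 1) - region$end)
  rep_ <- rep_[order(-rep_$len, rep_$disp, rep_$al), ]
  best <- rep_[1, ]
  region$start <- as.integer(best$al)
  region$end <- as.integer(best$ar + best$len - 1)
  region$att_left <- as.integer(best$al)
  region$att_right <- as.integer(best$ar)
  region$att_len <- as.integer(best$len)
  region
}

#' Marker-lookup hit provider
#'
#' The synthetic stand-in for an HMM scan against virus orthologous group
#' databases: an ORF "hits" when it contains at least `min_windows` marker
#' k-mer window positions.
#'
#' @param marker_set Character vector of marker k-mers.
#' @param k K-mer length.
#' @param min_windows Marker windows required for a hit (default 1).
#' @return A function mapping a tibble of ORFs with `marker_windows`
#'   counts (or raw sequences) to a tibble with `hit` and `score`.
#' @export
hit_provider_markers <- function(marker_set, k = 12, min_windows = 1) {
  force(marker_set); force(k); force(min_windows)
  function(orfs, seq = NULL) {
    if (!"marker_windows" %in% names(orfs)) {
      if (is.null(seq)) stop("need marker_windows column or contig sequence")
      hits <- marker_hit_positions(seq, marker_set, k)
      st <- orf_marker_stats(hits, orfs, k)
      orfs$marker_windows <- st$marker_windows
    }
    tibble(hit = orfs$marker_windows >= min_windows,
           score = orfs$marker_windows)
  }
}

#' Profile-HMM hit provider
#'
#' Adapter for verifying candidate regions against a user-supplied HMM
#' file (e.g. virus orthologous group profiles) with the `hmmsearch`
#' executable. Translated ORF sequences are scanned; an ORF hits when its
#' best full-sequence E-value is at most `evalue`.
#'
#' @param hmm_path Path to a profile HMM file.
#' @param evalue Significance threshold (default 1e-5).
#' @param hmmsearch Path to the `hmmsearch` binary.
#' @return A hit-provider function (see [hit_provider_markers()]).
#' @export
hit_provider_hmmer <- function(hmm_path, evalue = 1e-5,
                               hmmsearch = Sys.which("hmmsearch")) {
  if (!file.exists(hmm_path))
    stop("HMM file not found: ", hmm_path)
  if (!nzchar(hmmsearch))
    stop("hmmsearch executable not found on PATH")
  function(orfs, seq = NULL) {
    if (is.null(seq)) stop("the HMM provider needs the contig sequence")
    aa <- vapply(seq_len(nrow(orfs)), function(i) {
      s <- substr(seq, orfs$start[i], orfs$end[i])
      if (orfs$strand[i] == "-")
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      s <- substr(s, 1, nchar(s) - nchar(s) %% 3)
      as.character(Biostrings::translate(Biostrings::DNAString(s),
                                         if.fuzzy.codon = "solve"))
    }, character(1))
    faa <- tempfile(fileext = ".faa"); tbl <- tempfile(fileext = ".tbl")
    on.exit(unlink(c(faa, tbl)))
    writeLines(paste0(">orf", seq_along(aa), "\n", gsub("\\*", "", aa)), faa)
    system2(hmmsearch, c("--tblout", tbl, "-E", format(evalue), "--noali",
                         shQuote(hmm_path), shQuote(faa)),
            stdout = FALSE, stderr = FALSE)
    hits_tbl <- tryCatch(read.table(tbl, comment.char = "#",
                                    stringsAsFactors = FALSE),
                         error = function(e) NULL)
    hit_ids <- if (is.null(hits_tbl)) character(0) else unique(hits_tbl[[1]])
    tibble(hit = paste0("orf", seq_len(nrow(orfs))) %in% hit_ids,
           score = as.numeric(paste0("orf", seq_len(nrow(orfs))) %in% hit_ids))
  }
}

default_phage_tokens <- function() {
  c("phage", "prophage", "integrase", "capsid", "tail", "terminase", "portal")
}

#' Verify a candidate region with annotation and database evidence
#'
#' A region is kept iff it has at least `min_genes` phage-predicted genes
#' and either at least `min_phage_genes` of its ORFs carry a phage token in
#' their annotation, or at least one ORF has a provider hit. The verified
#' fraction is the bp of hit ORFs divided by the region bp. Regions that
#' fail keep their coordinates and get `status = "discarded"` with a
#' reason; all predictions, kept or not, are reported.
#'
#' @param region One-row region tibble.
#' @param orfs ORFs of the contig with `annotation` and `hit` columns.
#' @param min_phage_genes Annotated phage genes required (default 1).
#' @param tokens Case-insensitive annotation tokens counted as phage.
#' @return The region row with `phage_annotated_genes`,
#'   `verified_bp_fraction`, `status`, `discard_reason` filled in.
#' @export
verify_region <- function(region, orfs, min_phage_genes = 1,
                          tokens = default_phage_tokens()) {
  mid <- (orfs$start + orfs$end) / 2
  sel <- orfs[mid >= region$start & mid <= region$end, ]
  pat <- paste(tokens, collapse = "|")
  n_annot <- sum(grepl(pat, sel$annotation, ignore.case = TRUE))
  hits <- sel[which(sel$hit), ]
  vbp <- if (nrow(hits))
    sum(pmin(hits$end, region$end) - pmax(hits$start, region$start) + 1) else 0
  region$phage_annotated_genes <- n_annot
  region$verified_bp_fraction <- vbp / (region$end - region$start + 1)
  if (identical(region$status, "pending")) {
    if (n_annot >= min_phage_genes || nrow(hits) >= 1) {
      region$status <- "kept"
    } else {
      region$status <- "discarded"
      region$discard_reason <- "no_phage_evidence"
    }
  }
  region
}

#' Detect prophages in a genome
#'
#' The full compositional pipeline on each retained contig: ORFs (CDS
#' features when present, internal ORF calling otherwise), per-ORF raw
#' signals (length, strand, marker k-mer score, GC/AT skew deviations),
#' sliding-window features, random-forest classification, assembly of
#' phage-predicted runs into candidate regions, direct-repeat boundary
#' refinement, and evidence-based verification. Discarded candidates are
#' reported alongside kept ones, with reasons.
#'
#' @param genome A [genome_record()] (after [filter_assembly()]).
#' @param model A [train_classifier()] fit.
#' @param marker_set The phage marker k-mer set used for scoring.
#' @param config A [run_config()] list of pipeline parameters.
#' @param hit_provider Verification hit provider; defaults to the marker
#'   lookup over `marker_set`.
#' @return Tibble of prophage regions (kept and discarded), one row per
#'   candidate, with att coordinates, gene counts, verified fraction and
#'   status; attribute `n_orfs` records the ORF count scanned.
#' @export
detect <- function(genome, model, marker_set, config = run_config(),
                   hit_provider = NULL) {
  stopifnot(inherits(genome, "genome_record"),
            inherits(model, "prophage_classifier"))
  if (is.null(genome$contigs)) stop("detection needs sequence data")
  if (is.null(hit_provider))
    hit_provider <- hit_provider_markers(marker_set, config$kmer_k)
  keep <- genome$contig_lengths$length >= config$min_contig_len
  if (!any(keep)) {
    message("genome '", genome$accession, "': no contig reaches ",
            config$min_contig_len, " bp; nothing to scan")
    return(empty_regions())
  }
  baseline <- genome_baseline_skews(genome)
  out <- list()
  n_orfs_total <- 0L
  for (cid in genome$contig_lengths$contig_id[keep]) {
    seq <- contig_seq(genome, cid)
    orfs <- genome$cds[genome$cds$contig_id == cid, ]
    if (!nrow(orfs)) orfs <- call_orfs(seq, config$min_orf_len, contig_id = cid)
    if (!nrow(orfs)) next
    orfs <- arrange(orfs, .data$start, .data$end)
    n_orfs_total <- n_orfs_total + nrow(orfs)
    hits_vec <- marker_hit_positions(seq, marker_set, config$kmer_k)
    st <- orf_marker_stats(hits_vec, orfs, config$kmer_k)
    orfs$marker_windows <- st$marker_windows
    orfs$phage_kmer_score <- st$phage_kmer_score
    orfs <- compute_skews(seq, orfs, baseline)
    met <- window_metrics(orfs, config$window_size)
    prob <- predict(model, met, type = "prob")
    pred <- mutate(met, phage = prob >= model$threshold, phage_prob = prob)
    regions <- assemble_regions(pred, min_genes = config$number,
                                gap_tolerance = config$gap_tolerance)
    if (!nrow(regions)) next
    hp <- hit_provider(orfs, seq = seq)
    orfs$hit <- hp$hit
    regions <- bind_rows(lapply(seq_len(nrow(regions)), function(i) {
      r <- regions[i, ]
      if (identical(r$status, "pending"))
        r <- refine_boundaries(r, seq, config$extra_dna, config$min_repeat_len)
      verify_region(r, orfs, min_phage_genes = config$phage_genes,
                    tokens = config$annotation_tokens)
    }))
    out[[cid]] <- regions
  }
  res <- if (length(out)) bind_rows(out) else empty_regions()
  res <- mutate(res, accession = genome$accession, .before = 1)
  attr(res, "n_orfs") <- n_orfs_total
  res
}

empty_regions <- function() {
  tibble(contig_id = character(), start = integer(), end = integer(),
         n_genes = integer(), first_orf = integer(), last_orf = integer(),
         status = character(), discard_reason = character(),
         att_left = integer(), att_right = integer(), att_len = integer(),
         phage_annotated_genes = integer(), verified_bp_fraction = numeric())
}

#' Label cohort ORFs with simulator truth and build training data
#'
#' @param cohort A [generate_cohort()] result with sequences.
#' @param config A [run_config()].
#' @param genomes Subset of genome indices to use (default all).
#' @return List with `metrics` (feature tibble) and `labels`
#'   (`host`/`phage` factor): ORFs whose midpoint lies inside a retained
#'   planted prophage are `phage`.
#' @export
build_training_data <- function(cohort, config = run_config(), genomes = NULL) {
  stopifnot(inherits(cohort, "prophage_cohort"))
  idx <- genomes %||% seq_along(cohort$genomes)
  mets <- list(); labs <- list()
  for (i in idx) {
    g <- cohort$genomes[[i]]
    tr <- cohort$truth[cohort$truth$accession == g$accession &
                         cohort$truth$retained, ]
    baseline <- genome_baseline_skews(g)
    for (cid in names(g$contigs)) {
      seq <- contig_seq(g, cid)
      orfs <- g$cds[g$cds$contig_id == cid, ]
      if (!nrow(orfs)) next
      orfs <- arrange(orfs, .data$start, .data$end)
      hv <- marker_hit_positions(seq, cohort$marker_set, config$kmer_k)
      st <- orf_marker_stats(hv, orfs, config$kmer_k)
      orfs$marker_windows <- st$marker_windows
      orfs$phage_kmer_score <- st$phage_kmer_score
      orfs <- compute_skews(seq, orfs, baseline)
      met <- window_metrics(orfs, config$window_size)
      mid <- (met$start + met$end) / 2
      trc <- tr[tr$contig_id == cid, ]
      inside <- rep(FALSE, nrow(met))
      for (j in seq_len(nrow(trc)))
        inside <- inside | (mid >= trc$start[j] & mid <= trc$end[j])
      mets[[length(mets) + 1L]] <- met
      labs[[length(labs) + 1L]] <- ifelse(inside, "phage", "host")
    }
  }
  list(metrics = bind_rows(mets),
       labels = factor(unlist(labs), levels = c("host", "phage")))
}

#' Region-level recovery against planted truth
#'
#' Matches kept regions to retained planted prophages at a reciprocal
#' overlap threshold: a pair matches when the intersection covers at least
#' `min_overlap` of both the prediction and the truth region.
#'
#' @param regions Detector output (kept and discarded; only kept regions
#'   are scored).
#' @param truth Cohort truth rows.
#' @param min_overlap Reciprocal overlap threshold (default 0.5).
#' @return One-row tibble: `n_truth`, `n_kept`, `matched_truth`,
#'   `matched_pred`, `sensitivity`, `precision`.
#' @export
region_recovery <- function(regions, truth, min_overlap = 0.5) {
  truth <- truth[truth$retained, ]
  kept <- regions[regions$status == "kept", ]
  if (!nrow(truth) || !nrow(kept)) {
    return(tibble(n_truth = nrow(truth), n_kept = nrow(kept),
                  matched_truth = 0L, matched_pred = 0L,
                  sensitivity = ifelse(nrow(truth) == 0, NA_real_, 0),
                  precision = ifelse(nrow(kept) == 0, NA_real_, 0)))
  }
  key_t <- paste(truth$accession, truth$contig_id)
  key_p <- paste(kept$accession, kept$contig_id)
  shared <- intersect(unique(key_t), unique(key_p))
  m_t <- logical(nrow(truth)); m_p <- logical(nrow(kept))
  for (kk in shared) {
    ti <- which(key_t == kk); pi <- which(key_p == kk)
    tr <- IRanges::IRanges(truth$start[ti], truth$end[ti])
    pr <- IRanges::IRanges(kept$start[pi], kept$end[pi])
    ov <- IRanges::findOverlaps(pr, tr)
    if (!length(ov)) next
    w <- IRanges::width(IRanges::pintersect(pr[S4Vectors::queryHits(ov)],
                                            tr[S4Vectors::subjectHits(ov)]))
    good <- w >= min_overlap * IRanges::width(pr[S4Vectors::queryHits(ov)]) &
      w >= min_overlap * IRanges::width(tr[S4Vectors::subjectHits(ov)])
    m_p[pi[S4Vectors::queryHits(ov)[good]]] <- TRUE
    m_t[ti[S4Vectors::subjectHits(ov)[good]]] <- TRUE
  }
  tibble(n_truth = nrow(truth), n_kept = nrow(kept),
         matched_truth = sum(m_t), matched_pred = sum(m_p),
         sensitivity = mean(m_t), precision = mean(m_p))
}

#' Export detector regions as GFF3
#'
#' Writes one `prophage` feature per region (1-based inclusive
#' coordinates) with `n_genes`, att coordinates, `verified_bp_fraction`,
#' `status` and `discard_reason` attributes.
#'
#' @param regions Detector output for one genome.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_regions_gff3 <- function(regions, path) {
  if (!nrow(regions)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = regions$contig_id,
    ranges = IRanges::IRanges(regions$start, regions$end),
    strand = "*",
    type = "prophage",
    n_genes = regions$n_genes,
    att_left = regions$att_left,
    att_right = regions$att_right,
    att_len = regions$att_len,
    verified_bp_fraction = signif(regions$verified_bp_fraction, 6),
    status = regions$status,
    discard_reason = regions$discard_reason)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
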