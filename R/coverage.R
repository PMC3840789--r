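# Strand-aware fractional coverage. Footprints are mapped to estimated
# P-sites by pruning 12 nt from each end of the alignment and spreading one
# read evenly over the remaining n = l - 24 positions; mRNA fragments are
# spread 1/l over their full alignment. Alignment tibbles carry: qname,
# chrom, strand, pos (0-based leftmost), len, mm (mismatch string or NA),
# and optionally a `blocks` list-column of covered genomic positions for
# spliced alignments.

PSITE_TRIM <- 12L
MIN_FOOTPRINT <- 25L

covered_positions <- function(read_row) {
  if ("blocks" %in% names(read_row) && !is.null(read_row$blocks)) {
    bl <- read_row$blocks[[1]]
    if (!is.null(bl)) return(sort(bl))
  }
  seq.int(read_row$pos, read_row$pos + read_row$len - 1L)
}

#' P-site weights of a single footprint alignment
#'
#' Prunes 12 nt from each end of the alignment and spreads one read evenly
#' over the n = l - 24 remaining positions (0.5 per position for a 26-mer,
#' 1.0 for a 25-mer). Reads shorter than 25 nt are rejected.
#'
#' @param read One-row alignment tibble.
#' @return Tibble with `pos` and `weight`; weights sum to 1.
#' @export
assign_psite_weights <- function(read) {
  if (read$len < MIN_FOOTPRINT) stop("footprint shorter than 25 nt")
  cp <- covered_positions(read)
  n <- length(cp) - 2L * PSITE_TRIM
  keep <- cp[(PSITE_TRIM + 1L):(PSITE_TRIM + n)]
  tibble(pos = keep, weight = 1 / n)
}

#' Full-length weights of a single mRNA-fragment alignment
#'
#' Each covered genomic position receives 1/l; for spliced fragments only
#' exonic (aligned) positions are covered.
#'
#' @param read One-row alignment tibble.
#' @return Tibble with `pos` and `weight`; weights sum to 1.
#' @export
assign_mrna_weights <- function(read) {
  cp <- covered_positions(read)
  tibble(pos = cp, weight = 1 / length(cp))
}

#' Build a coverage track from alignments
#'
#' Applies the P-site rule (`class = "footprint"`) or the spread rule
#' (`class = "mrna"`) to every alignment and accumulates fractional weights
#' per genomic position and strand. Footprints shorter than 25 nt are
#' rejected and tallied in the `n_rejected` attribute. Total weight equals
#' the number of counted reads (asserted to 1e-6 per read).
#'
#' @param alignments Alignment tibble.
#' @param class `"footprint"` or `"mrna"`.
#' @return Coverage tibble (`chrom`, `strand`, `pos`, `weight`) with
#'   attributes `class`, `n_reads`, `n_rejected`.
#' @export
coverage_track <- function(alignments, class = c("footprint", "mrna")) {
  class <- match.arg(class)
  aln <- alignments
  n_rejected <- 0L
  if (class == "footprint") {
    n_rejected <- sum(aln$len < MIN_FOOTPRINT)
    aln <- filter(aln, .data$len >= MIN_FOOTPRINT)
  }
  has_blocks <- "blocks" %in% names(aln) & !map_lgl(
    if ("blocks" %in% names(aln)) aln$blocks else vector("list", nrow(aln)),
    is.null)
  plain <- aln[!has_blocks, ]
  spliced <- aln[has_blocks, ]
  pieces <- list()
  if (nrow(plain) > 0) {
    if (class == "footprint") {
      n <- plain$len - 2L * PSITE_TRIM
      starts <- plain$pos + PSITE_TRIM
    } else {
      n <- plain$len
      starts <- plain$pos
    }
    idx <- rep.int(seq_len(nrow(plain)), n)
    pieces$plain <- tibble(
      chrom = plain$chrom[idx], strand = plain$strand[idx],
      pos = rep.int(starts, n) + (sequence(n) - 1L),
      weight = rep.int(1 / n, n)
    )
  }
  if (nrow(spliced) > 0) {
    fun <- if (class == "footprint") assign_psite_weights else assign_mrna_weights
    pieces$spliced <- bind_rows(map(seq_len(nrow(spliced)), function(i) {
      w <- fun(spliced[i, ])
      w$chrom <- spliced$chrom[i]
      w$strand <- spliced$strand[i]
      w
    }))
  }
  track <- bind_rows(pieces) |>
    group_by(.data$chrom, .data$strand, .data$pos) |>
    summarise(weight = sum(.data$weight), .groups = "drop")
  n_reads <- nrow(aln)
  if (n_reads > 0) {
    stopifnot(abs(sum(track$weight) - n_reads) <= 1e-6 * n_reads)
  }
  structure(track, class = c("coverage_track", class(track)),
            track_class = class, n_reads = n_reads, n_rejected = n_rejected)
}

# Sum of track weights over a position set (chrom, strand, pos tibble).
region_count <- function(track, positions) {
  if (nrow(positions) == 0) return(0)
  hit <- inner_join(track,
                    distinct(positions, .data$chrom, .data$strand, .data$pos),
                    by = c("chrom", "strand", "pos"))
  sum(hit$weight)
}

#' Reads per kilobase per million (RPKM)
#'
#' `sum(weights over positions) / (|positions| / 1000) / (library_size / 1e6)`.
#'
#' @param track Coverage track.
#' @param positions Tibble of countable positions (`chrom`, `strand`, `pos`).
#' @param library_size Total number of aligned reads in the library.
#' @return RPKM value.
#' @export
rpkm <- function(track, positions, library_size) {
  if (nrow(positions) == 0) stop("empty position set: RPKM undefined")
  region_count(track, positions) /
    (nrow(positions) / 1000) / (library_size / 1e6)
}

#' Area under the Lorenz curve of coverage evenness
#'
#' Per-position weights (zeros included for uncovered positions) are sorted
#' ascending and the area under the cumulative-share curve is computed by
#' trapezoids. Perfectly uniform coverage gives 0.5; concentration of all
#' weight on few positions drives the area toward 0.
#'
#' @param track Coverage track.
#' @param positions Position tibble over which evenness is measured.
#' @return Area in [0, 0.5], or NA if the region has no coverage.
#' @export
lorenz_evenness <- function(track, positions) {
  if (nrow(positions) == 0) stop("need at least one position")
  pos <- distinct(positions, .data$chrom, .data$strand, .data$pos)
  hit <- left_join(pos, track, by = c("chrom", "strand", "pos"))
  w <- sort(dplyr::coalesce(hit$weight, 0))
  if (sum(w) == 0) return(NA_real_)
  y <- c(0, cumsum(w) / sum(w))
  x <- seq(0, 1, length.out = length(y))
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Peak-mask position presets
#'
#' Genomic positions excluded from density totals to avoid initiation and
#' termination peaks, in transcript coordinates around each transcript's
#' start and stop codon. Two presets exist: `"te"` (9 nt preceding the
#' start codon, 15 nt following it, 15 nt preceding and 15 nt following
#' the stop codon) used for regional translation-efficiency measurements,
#' and `"readthrough"` (12 nt following the start codon, 15 nt preceding
#' the stop codon, 9 nt following it) used for readthrough rates; the
#' extension-side windows of the readthrough preset are applied per
#' candidate by [readthrough_rate()].
#'
#' @param annotation Exon-level annotation tibble.
#' @param preset `"te"` or `"readthrough"`.
#' @return Tibble of masked positions (`chrom`, `strand`, `pos`).
#' @export
peak_mask <- function(annotation, preset = c("te", "readthrough")) {
  preset <- match.arg(preset)
  txs <- split_transcripts(annotation)
  bind_rows(map(txs, function(tx) {
    pos <- tx_positions(tx)
    b <- tx_cds_bounds(tx)
    s <- b[["cds"]]; t <- b[["stop"]]
    off <- if (preset == "te") {
      c(seq.int(s - 9L, s - 1L), seq.int(s + 3L, s + 17L),
        seq.int(t - 15L, t - 1L), seq.int(t + 3L, t + 17L))
    } else {
      c(seq.int(s + 3L, s + 14L), seq.int(t - 15L, t - 1L),
        seq.int(t + 3L, t + 11L))
    }
    off <- off[off >= 0L & off < length(pos)]
    tibble(chrom = tx$chrom[1], strand = tx$strand[1], pos = pos[off + 1L])
  })) |> distinct()
}

#' Regional translation efficiency
#'
#' Ratio of footprint to mRNA-fragment density per region (5'UTR, CDS,
#' 3'UTR) of each locus, excluding ambiguously labelled positions and
#' peak-mask windows. Regions with fewer than `min_mrna` mRNA counts are
#' flagged untestable and get no TE.
#'
#' @param labelled Labelled locus positions from [label_regions()].
#' @param fp_track,mrna_track Coverage tracks.
#' @param fp_library,mrna_library Library sizes (aligned reads).
#' @param mask Peak-mask tibble from [peak_mask()], or NULL.
#' @param min_mrna Count threshold for a testable region, default 128.
#' @return Tibble per locus and region with counts, RPKM and `te`.
#' @export
translation_efficiency <- function(labelled, fp_track, mrna_track,
                                   fp_library, mrna_library, mask = NULL,
                                   min_mrna = 128) {
  use <- filter(labelled, .data$label %in% c("5UTR", "CDS", "3UTR"))
  if (!is.null(mask) && nrow(mask) > 0) {
    use <- anti_join(use, mask, by = c("chrom", "strand", "pos"))
  }
  regions <- use |> group_by(.data$locus_id, .data$label)
  keys <- dplyr::group_keys(regions)
  rows <- dplyr::group_split(regions)
  bind_rows(map2(rows, seq_len(nrow(keys)), function(posn, i) {
    fp_n <- region_count(fp_track, posn)
    mr_n <- region_count(mrna_track, posn)
    testable <- mr_n >= min_mrna
    tibble(
      locus_id = keys$locus_id[i], region = keys$label[i],
      n_positions = nrow(posn),
      fp_count = fp_n, mrna_count = mr_n,
      fp_rpkm = fp_n / (nrow(posn) / 1000) / (fp_library / 1e6),
      mrna_rpkm = mr_n / (nrow(posn) / 1000) / (mrna_library / 1e6),
      testable = testable,
      te = if (testable) (fp_n / fp_library) / (mr_n / mrna_library)
           else NA_real_
    )
  }))
}
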