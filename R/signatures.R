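# Diagnostics distinguishing true translation from contaminant density:
# metagene profiles, ribosome release scores, read-length distributions,
# triplet phasing.

#' Select regions of interest for metagene analysis
#'
#' Keeps genes in which (a) all transcripts share one annotated start (or
#' stop) codon, (b) all transcripts cover identical genomic positions over
#' the window, (c) no window position is degenerate, and (d) the coding
#' subregion holds at least `min_reads` footprint reads.
#'
#' @param annotation Exon-level annotation tibble.
#' @param track Footprint coverage track.
#' @param anchor `"start"` or `"stop"`.
#' @param window Offsets around the anchor, default `c(-50, 50)`.
#' @param degenerate Optional degenerate-position tibble.
#' @param min_reads Minimum reads in the coding subregion, default 10.
#' @return Tibble of ROI transcripts (`transcript_id`).
#' @export
select_metagene_rois <- function(annotation, track,
                                 anchor = c("stop", "start"),
                                 window = c(-50L, 50L), degenerate = NULL,
                                 min_reads = 10) {
  anchor <- match.arg(anchor)
  degen_key <- if (!is.null(degenerate)) {
    paste(degenerate$chrom, degenerate$pos)
  } else character(0)
  keep <- map(split(annotation, annotation$gene_id), function(ga) {
    txs <- split_transcripts(ga)
    anchors <- map_int(txs, function(tx) {
      b <- tx_cds_bounds(tx)
      pos <- tx_positions(tx)
      pos[(if (anchor == "start") b[["cds"]] else b[["stop"]]) + 1L]
    })
    if (length(unique(anchors)) != 1) return(NULL)
    wins <- map(txs, function(tx) roi_window_positions(tx, anchor, window))
    if (length(unique(map_chr(wins, function(w) {
      paste(w$pos, collapse = ",")
    }))) != 1) {
      return(NULL)
    }
    w <- wins[[1]]
    if (any(paste(w$chrom, w$pos) %in% degen_key)) return(NULL)
    cds_part <- filter(w, .data$coding)
    if (region_count(track, cds_part) < min_reads) return(NULL)
    tibble(transcript_id = names(txs)[1])
  })
  bind_rows(keep)
}

# Window positions of one transcript around an anchor, in transcript
# orientation, with offset and coding-subregion flag.
roi_window_positions <- function(tx, anchor, window) {
  pos <- tx_positions(tx)
  b <- tx_cds_bounds(tx)
  a <- if (anchor == "start") b[["cds"]] else b[["stop"]]
  off <- seq.int(window[1], window[2])
  idx <- a + off
  ok <- idx >= 0L & idx < length(pos)
  tibble(
    chrom = tx$chrom[1], strand = tx$strand[1],
    offset = off[ok], pos = pos[idx[ok] + 1L],
    coding = idx[ok] >= b[["cds"]] & idx[ok] <= b[["stop"]] + 2L
  )
}

#' Metagene profile of normalised ribosome density
#'
#' For each ROI builds the coverage vector over the window anchored at its
#' start or stop codon, normalises it to the mean footprint density over
#' the ROI's coding subregion (excluding a 3-codon buffer adjacent to the
#' anchored codon, to avoid peak bleedthrough), and reports the per-offset
#' median across ROIs. The median is invariant to per-ROI scaling.
#'
#' @param rois Tibble with `transcript_id` (e.g. from
#'   [select_metagene_rois()]).
#' @param annotation Exon-level annotation tibble.
#' @param track Footprint coverage track.
#' @param anchor `"start"` or `"stop"`.
#' @param window Offsets around the anchor, default `c(-50, 50)`.
#' @return A `metagene_profile` tibble: `offset`, `median_density`,
#'   `n_roi`.
#' @export
metagene_profile <- function(rois, annotation, track,
                             anchor = c("stop", "start"),
                             window = c(-50L, 50L)) {
  anchor <- match.arg(anchor)
  if (nrow(rois) < 2) stop("need at least 2 ROIs")
  txs <- split_transcripts(annotation)
  mats <- map(rois$transcript_id, function(txid) {
    tx <- txs[[txid]]
    w <- roi_window_positions(tx, anchor, window)
    cov <- left_join(w, track, by = c("chrom", "strand", "pos"))
    cov$weight <- dplyr::coalesce(cov$weight, 0)
    # normaliser: mean coverage over the full coding region minus a
    # 3-codon buffer at the anchored codon
    pos <- tx_positions(tx)
    b <- tx_cds_bounds(tx)
    cds_off <- seq.int(b[["cds"]], b[["stop"]] + 2L)
    buffer <- if (anchor == "start") {
      seq.int(b[["cds"]], b[["cds"]] + 8L)
    } else {
      seq.int(b[["stop"]] - 9L, b[["stop"]] + 2L)
    }
    norm_off <- setdiff(cds_off, buffer)
    norm_tbl <- tibble(chrom = tx$chrom[1], strand = tx$strand[1],
                       pos = pos[norm_off + 1L])
    denom <- region_count(track, norm_tbl) / nrow(norm_tbl)
    if (denom <= 0) return(NULL)
    tibble(offset = cov$offset, value = cov$weight / denom)
  })
  mats <- mats[!map_lgl(mats, is.null)]
  prof <- bind_rows(mats) |>
    group_by(.data$offset) |>
    summarise(median_density = median(.data$value), .groups = "drop") |>
    mutate(n_roi = length(mats))
  structure(prof, class = c("metagene_profile", class(prof)),
            anchor = anchor)
}

#' Ribosome release score
#'
#' Ratio of footprint counts in the 5-codon window immediately downstream
#' of a codon to the counts in the 5-codon window immediately upstream
#' (the codon itself excluded). At efficient termination sites the score
#' approaches zero. Undefined (NA, no pseudocount) when the upstream
#' window is empty.
#'
#' @param codons Tibble with `chrom`, `strand`, `pos` (genomic coordinate
#'   of the codon's first base, mRNA sense).
#' @param track Footprint coverage track.
#' @return Tibble with `upstream_count`, `downstream_count`, `score`.
#' @export
release_score <- function(codons, track) {
  res <- map(seq_len(nrow(codons)), function(i) {
    r <- codons[i, ]
    sgn <- if (r$strand == "+") 1L else -1L
    up <- r$pos + sgn * seq.int(-15L, -1L)
    down <- r$pos + sgn * seq.int(3L, 17L)
    upc <- region_count(track, tibble(chrom = r$chrom, strand = r$strand,
                                      pos = up))
    dnc <- region_count(track, tibble(chrom = r$chrom, strand = r$strand,
                                      pos = down))
    tibble(upstream_count = upc, downstream_count = dnc,
           score = if (upc > 0) dnc / upc else NA_real_)
  })
  bind_cols(codons, bind_rows(res))
}

#' Read-length distribution over a region
#'
#' Fraction of footprints of each length (25-35 nt) among reads whose
#' P-site positions overlap the region.
#'
#' @param alignments Footprint alignment tibble.
#' @param positions Region position tibble (`chrom`, `strand`, `pos`).
#' @param lengths Histogram support, default 25:35.
#' @return Tibble with `len`, `n`, `fraction`.
#' @export
length_distribution <- function(alignments, positions, lengths = 25:35) {
  if (nrow(alignments) == 0) stop("need at least one read")
  aln <- filter(alignments, .data$len >= MIN_FOOTPRINT)
  n <- aln$len - 2L * PSITE_TRIM
  idx <- rep.int(seq_len(nrow(aln)), n)
  psites <- tibble(
    read = idx, chrom = aln$chrom[idx], strand = aln$strand[idx],
    pos = rep.int(aln$pos + PSITE_TRIM, n) + (sequence(n) - 1L)
  )
  hits <- inner_join(psites,
                     distinct(positions, .data$chrom, .data$strand,
                              .data$pos),
                     by = c("chrom", "strand", "pos"))
  in_region <- unique(hits$read)
  lens <- aln$len[in_region]
  tab <- table(factor(lens, levels = lengths))
  tibble(len = lengths, n = as.integer(tab),
         fraction = if (sum(tab) > 0) as.numeric(tab) / sum(tab) else 0)
}

#' Total variation distance between two length distributions
#'
#' @param d1,d2 Outputs of [length_distribution()].
#' @return Half the L1 distance between the two `fraction` vectors.
#' @export
tv_distance <- function(d1, d2) {
  sum(abs(d1$fraction - d2$fraction)) / 2
}

#' Triplet phasing test
#'
#' Tallies the reading frame of footprints of one length (28-mers by
#' default, the best-phased population) in each region class, using the
#' frame of the 5'-most pruned P-site position relative to the host CDS
#' frame. Expected frame proportions come from matched mRNA fragments in
#' the same region (controlling cloning biases; `expected = "uniform"`
#' substitutes a uniform null) and footprint counts are tested against
#' them with a chi-squared goodness-of-fit test, dof = 2.
#'
#' @param fp_aln,mrna_aln Alignment tibbles.
#' @param regions Tibble with `region` (class label), `chrom`, `strand`,
#'   `pos` and `frame` (0/1/2 relative to the CDS frame) for every
#'   position; see [region_frames()].
#' @param read_length Footprint length tallied, default 28.
#' @param expected `"mrna"` or `"uniform"`.
#' @return A `phasing_table` tibble: per region, counts per frame,
#'   chi-squared statistic, dof, p.
#' @export
phasing_test <- function(fp_aln, mrna_aln, regions, read_length = 28L,
                         expected = c("mrna", "uniform")) {
  expected <- match.arg(expected)
  fp <- filter(fp_aln, .data$len == read_length)
  fp_pos <- mutate(fp,
    pos = if_else(.data$strand == "+", .data$pos + PSITE_TRIM,
                  .data$pos + .data$len - 1L - PSITE_TRIM))
  mr_pos <- mutate(mrna_aln,
    pos = if_else(.data$strand == "+", .data$pos,
                  .data$pos + .data$len - 1L))
  tally <- function(reads) {
    inner_join(select(reads, "chrom", "strand", "pos"), regions,
               by = c("chrom", "strand", "pos")) |>
      count(.data$region, .data$frame) |>
      tidyr::complete(region = unique(regions$region), frame = 0:2,
                      fill = list(n = 0L))
  }
  fp_t <- tally(fp_pos)
  mr_t <- tally(mr_pos)
  out <- map(unique(regions$region), function(rg) {
    o <- filter(fp_t, .data$region == rg) |> arrange(.data$frame)
    m <- filter(mr_t, .data$region == rg) |> arrange(.data$frame)
    e_prop <- if (expected == "uniform") rep(1 / 3, 3) else {
      if (sum(m$n) == 0) stop("no mRNA fragments in region ", rg)
      m$n / sum(m$n)
    }
    if (any(e_prop == 0)) stop("expected frame count of zero in region ", rg)
    gof <- chi_squared_gof(o$n, e_prop)
    tibble(region = rg, frame0 = o$n[1], frame1 = o$n[2], frame2 = o$n[3],
           mrna_frame0 = m$n[1], mrna_frame1 = m$n[2], mrna_frame2 = m$n[3],
           statistic = gof$statistic, dof = gof$dof, p = gof$p)
  }) |> bind_rows()
  structure(out, class = c("phasing_table", class(out)))
}

#' Per-position reading frames of candidate regions
#'
#' Builds the `regions` input of [phasing_test()] for CDS, extension and
#' distal-3'UTR classes, with frames measured relative to each
#' transcript's CDS frame.
#'
#' @param annotation Exon-level annotation tibble.
#' @param candidates Candidate tibble from [enumerate_candidates()]
#'   (tier-1 rows are used); NULL for CDS-only.
#' @return Tibble with `region`, `chrom`, `strand`, `pos`, `frame`.
#' @export
region_frames <- function(annotation, candidates = NULL) {
  txs <- split_transcripts(annotation)
  cds <- bind_rows(map(txs, function(tx) {
    pos <- tx_positions(tx)
    b <- tx_cds_bounds(tx)
    off <- seq.int(b[["cds"]], b[["stop"]] - 1L)
    tibble(region = "CDS", chrom = tx$chrom[1], strand = tx$strand[1],
           pos = pos[off + 1L], frame = (off - b[["cds"]]) %% 3L)
  }))
  if (is.null(candidates) || nrow(candidates) == 0) return(cds)
  c1 <- filter(candidates, .data$tier == 1)
  extra <- bind_rows(map(seq_len(nrow(c1)), function(i) {
    r <- c1[i, ]
    ep <- r$ext_pos[[1]]
    dp <- r$distal_pos[[1]]
    bind_rows(
      tibble(region = "extension", chrom = r$chrom, strand = r$strand,
             pos = ep, frame = (seq_along(ep) - 1L) %% 3L),
      tibble(region = "distal3UTR", chrom = r$chrom, strand = r$strand,
             pos = dp, frame = (seq_along(dp) - 1L) %% 3L)
    )
  }))
  bind_rows(cds, extra)
}
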