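# Candidate C-terminal extensions and readthrough quantification. An
# extension runs from the 3' edge of the annotated stop codon to the next
# in-frame stop codon, exclusive of both stops; its readthrough rate is the
# ratio of peak-masked footprint density (RPKM) in the extension to that in
# the CDS.

#' Genomic positions that disqualify an extension
#'
#' Union of all positions annotated as CDS or 5'UTR in any transcript plus
#' every exonic position of genes with an excluded biotype (tRNA, rRNA,
#' snRNA, snoRNA, miRNA, pre-miRNA). A candidate extension overlapping any
#' of these (on either strand) is dropped.
#'
#' @param annotation Exon-level annotation tibble.
#' @param excluded_biotypes Biotypes whose whole loci disqualify overlap.
#' @return Tibble with `chrom`, `pos`.
#' @export
candidate_exclusion_positions <- function(annotation,
                                          excluded_biotypes = c(
                                            "tRNA", "rRNA", "snRNA",
                                            "snoRNA", "miRNA", "pre_miRNA")) {
  txs <- split_transcripts(annotation)
  bind_rows(map(txs, function(tx) {
    lab <- tx_region_labels(tx)
    bad_bio <- "biotype" %in% names(tx) && tx$biotype[1] %in% excluded_biotypes
    keep <- if (bad_bio) lab else filter(lab, .data$label %in% c("CDS", "5UTR"))
    select(keep, "chrom", "pos")
  })) |> distinct()
}

#' Enumerate candidate C-terminal extensions
#'
#' For every coding transcript with an annotated 3'UTR, walks codons in
#' frame from the annotated stop to the next in-frame stop. A candidate is
#' kept when the extension is at least `min_codons` codons long, does not
#' overlap any disqualifying annotation, contains no methionine in its
#' first three codons (unless the gene is whitelisted), and is not
#' explained by an annotated isoform that omits the stop codon. One row is
#' emitted per unique (stop codon, next in-frame stop) pair; a second-tier
#' candidate beyond the extension's stop is emitted (`tier = 2`) for
#' double-readthrough scanning.
#'
#' @param annotation Exon-level annotation tibble.
#' @param genome Named character vector of chromosome sequences.
#' @param exclusions Tibble of disqualifying positions, e.g. from
#'   [candidate_exclusion_positions()]; NULL disables the overlap filter.
#' @param met_whitelist Gene ids exempt from the methionine rule.
#' @param min_codons Minimum extension length, default 5 codons.
#' @param distal_codons Distal 3'UTR window, default 40 codons.
#' @param distal_min_nt When the annotated distal 3'UTR is shorter, it is
#'   extended in uninterrupted genomic coordinates to this length
#'   (default 114 nt).
#' @return Candidate tibble; one row per candidate with list-columns
#'   `transcript_ids`, `ext_pos` (genomic positions, 5'->3'),
#'   `distal_pos`, `ext_stop_codon_pos`.
#' @export
enumerate_candidates <- function(annotation, genome, exclusions = NULL,
                                 met_whitelist = character(),
                                 min_codons = 5L, distal_codons = 40L,
                                 distal_min_nt = 114L) {
  txs <- split_transcripts(annotation)
  excl_key <- if (!is.null(exclusions)) {
    paste(exclusions$chrom, exclusions$pos)
  } else character(0)
  cds_of <- map_chr(txs, function(tx) {
    paste(tx$cds_start[1], tx$cds_stop[1], tx$chrom[1])
  })
  rows <- list()
  for (tx in txs) {
    if (is.na(tx$cds_start[1])) next
    seq_ <- tx_sequence(genome, tx)
    pos <- tx_positions(tx)
    b <- tx_cds_bounds(tx)
    t <- b[["stop"]]
    tx_len <- length(pos)
    if (t + 3L >= tx_len) {
      message("skipping ", tx$transcript_id[1], ": no annotated 3'UTR")
      next
    }
    # omitted-stop isoforms: another isoform of the gene whose CDS covers
    # this stop codon position as internal coding sequence
    sibs <- annotation[annotation$gene_id == tx$gene_id[1] &
                         annotation$transcript_id != tx$transcript_id[1], ]
    stop_genomic <- pos[t + 1L]
    if (nrow(sibs) > 0) {
      omit <- any(map_lgl(split_transcripts(sibs), function(sb) {
        if (is.na(sb$cds_start[1])) return(FALSE)
        sp <- tx_positions(sb)
        sbb <- tx_cds_bounds(sb)
        i <- match(stop_genomic, sp)
        !is.na(i) && (i - 1L) >= sbb[["cds"]] && (i - 1L) < sbb[["stop"]] &&
          sb$cds_stop[1] != tx$cds_stop[1]
      }))
      if (omit) next
    }
    tier_from <- t
    for (tier in 1:2) {
      u <- next_inframe_stop(seq_, tier_from + 3L)
      if (is.na(u)) break
      n_cod <- (u - tier_from - 3L) %/% 3L
      if (n_cod < min_codons) break
      ext_off <- seq.int(tier_from + 3L, u - 1L)
      first3 <- str_sub(seq_, tier_from + 4L, tier_from + 12L)
      has_met <- any(str_sub(first3, c(1, 4, 7), c(3, 6, 9)) == "ATG")
      if (has_met && !(tx$gene_id[1] %in% met_whitelist)) break
      ext_genomic <- pos[ext_off + 1L]
      if (length(excl_key) > 0 &&
          any(paste(tx$chrom[1], ext_genomic) %in% excl_key)) break
      # distal window: 40 codons past the extension's stop, extended in
      # genomic coordinates when the transcript ends early
      dist_off <- seq.int(u + 3L, u + 2L + 3L * distal_codons)
      inside <- dist_off[dist_off < tx_len]
      dist_genomic <- pos[inside + 1L]
      short <- max(distal_min_nt, 0L) - length(dist_genomic)
      if (length(dist_genomic) < distal_min_nt) {
        lastp <- if (length(dist_genomic) > 0) {
          dist_genomic[length(dist_genomic)]
        } else if (u + 2L < tx_len) pos[u + 3L] else pos[tx_len]
        step <- if (tx$strand[1] == "+") 1L else -1L
        dist_genomic <- c(dist_genomic, lastp + step * seq_len(short))
      }
      rows[[length(rows) + 1L]] <- tibble(
        candidate_id = paste0(tx$chrom[1], ":", pos[tier_from + 1L], "-",
                              pos[u + 1L], "(", tx$strand[1], ")"),
        tier = tier,
        gene_id = tx$gene_id[1], transcript_id = tx$transcript_id[1],
        chrom = tx$chrom[1], strand = tx$strand[1],
        stop_pos = pos[tier_from + 1L], next_stop_pos = pos[u + 1L],
        ext_codons = n_cod,
        ext_pos = list(ext_genomic),
        distal_pos = list(dist_genomic),
        ext_stop_codon_pos = list(pos[(u + 1L):(u + 3L)])
      )
      tier_from <- u
    }
  }
  if (length(rows) == 0) {
    return(tibble(candidate_id = character(0)))
  }
  out <- bind_rows(rows)
  # one candidate per unique (stop, next-stop) pair; isoforms collected
  out |>
    group_by(.data$candidate_id, .data$tier) |>
    summarise(
      gene_id = .data$gene_id[1], chrom = .data$chrom[1],
      strand = .data$strand[1], stop_pos = .data$stop_pos[1],
      next_stop_pos = .data$next_stop_pos[1],
      ext_codons = .data$ext_codons[1],
      transcript_ids = list(unique(.data$transcript_id)),
      same_cds = length(unique(cds_of[unique(.data$transcript_id)])) == 1,
      ext_pos = .data$ext_pos[1], distal_pos = .data$distal_pos[1],
      ext_stop_codon_pos = .data$ext_stop_codon_pos[1],
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$stop_pos, .data$tier)
}

# Peak-masked CDS positions of one transcript for the readthrough-rate
# preset: the 12 nt following the start codon and the 15 nt preceding the
# stop codon are excluded, and so are the start and stop codons
# themselves (the initiation/termination peaks are centred on them).
masked_cds_positions <- function(tx) {
  pos <- tx_positions(tx)
  b <- tx_cds_bounds(tx)
  s <- b[["cds"]]; t <- b[["stop"]]
  off <- seq.int(s + 15L, t - 16L)
  tibble(chrom = tx$chrom[1], strand = tx$strand[1], pos = pos[off + 1L])
}

# Peak-masked extension positions: drop the 9 nt following the upstream
# stop codon and the 15 nt preceding the extension's stop.
masked_ext_positions <- function(cand_row) {
  ep <- cand_row$ext_pos[[1]]
  n <- length(ep)
  if (n <= 24L) return(ep[0])
  ep[seq.int(10L, n - 15L)]
}

#' Readthrough rate of candidate extensions
#'
#' Computes peak-masked footprint RPKM in each candidate extension and its
#' CDS and their ratio rho. Among isoforms sharing the extension the
#' isoform minimising rho is reported. Candidates whose CDS has fewer than
#' `min_cds_reads` masked footprint reads are flagged untestable;
#' extensions too short to survive the mask (<= 24 nt) are flagged
#' rate-unmeasurable.
#'
#' @param candidates Candidate tibble from [enumerate_candidates()].
#' @param annotation Exon-level annotation tibble.
#' @param fp_track Footprint coverage track.
#' @param library_size Aligned footprint reads in the library.
#' @param min_cds_reads CDS footprint count floor, default 128.
#' @param extra_mask Optional tibble of additional positions to exclude
#'   (degenerate or multi-locus positions).
#' @return Record tibble: candidate columns plus `transcript_id` (chosen
#'   isoform), masked `cds_count`, `ext_count`, `cds_rpkm`, `ext_rpkm`,
#'   `rho`, `rate_measurable`, `testable`.
#' @export
readthrough_rate <- function(candidates, annotation, fp_track, library_size,
                             min_cds_reads = 128, extra_mask = NULL) {
  txs <- split_transcripts(annotation)
  drop_extra <- function(posn) {
    if (is.null(extra_mask) || nrow(extra_mask) == 0) return(posn)
    anti_join(posn, extra_mask, by = intersect(names(posn),
                                               c("chrom", "strand", "pos")))
  }
  recs <- map(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    mep <- masked_ext_positions(cand)
    ext_tbl <- drop_extra(tibble(chrom = cand$chrom, strand = cand$strand,
                                 pos = mep))
    per_iso <- map(cand$transcript_ids[[1]], function(txid) {
      cds_tbl <- drop_extra(masked_cds_positions(txs[[txid]]))
      cds_count <- region_count(fp_track, cds_tbl)
      cds_rpkm <- if (nrow(cds_tbl) > 0) {
        cds_count / (nrow(cds_tbl) / 1000) / (library_size / 1e6)
      } else NA_real_
      ext_count <- region_count(fp_track, ext_tbl)
      ext_rpkm <- if (nrow(ext_tbl) > 0) {
        ext_count / (nrow(ext_tbl) / 1000) / (library_size / 1e6)
      } else NA_real_
      rho <- if (!is.na(cds_rpkm) && cds_rpkm > 0 && !is.na(ext_rpkm)) {
        ext_rpkm / cds_rpkm
      } else NA_real_
      tibble(transcript_id = txid, cds_count = cds_count,
             cds_rpkm = cds_rpkm, ext_count = ext_count,
             ext_rpkm = ext_rpkm, rho = rho)
    }) |> bind_rows()
    pick <- if (all(is.na(per_iso$rho))) 1L else which.min(per_iso$rho)
    chosen <- per_iso[pick, ]
    bind_cols(
      select(cand, -"transcript_ids"),
      chosen,
      tibble(
        rate_measurable = length(cand$ext_pos[[1]]) > 24L,
        testable = chosen$cds_count >= min_cds_reads &&
          !is.na(chosen$cds_rpkm) && chosen$cds_rpkm > 0
      )
    )
  })
  bind_rows(recs)
}

#' Apply the candidate filters
#'
#' Evaluates, per record: (a) extension density >= `min_ext_rpkm`,
#' (b) readthrough rate >= `min_rho`, (c) fraction of extension positions
#' covered >= `min_coverage`, (d) first covered position within the first
#' quartile of the extension, (e) last covered position within the last
#' quartile, (f) density drop of at least `min_drop` into the first
#' `distal_nt` nucleotides of the distal 3'UTR. Also computes the maximum
#' covered-position gap (evenness proxy) and the footprint weight on the
#' extension's stop codon (sparse-relaxation peak).
#'
#' @param records Record tibble from [readthrough_rate()].
#' @param fp_track Footprint coverage track.
#' @param library_size Aligned footprint reads.
#' @param min_ext_rpkm,min_rho,min_coverage,min_drop,distal_nt Filter
#'   thresholds (defaults 0.2 RPKM, 0.001, 0.10, 0.75, 114 nt).
#' @param max_gap_frac Evenness proxy: maximum gap between covered
#'   positions as a fraction of extension length, default 0.5.
#' @return `records` with filter flags and supporting statistics added.
#' @export
apply_filters <- function(records, fp_track, library_size,
                          min_ext_rpkm = 0.2, min_rho = 0.001,
                          min_coverage = 0.10, min_drop = 0.75,
                          distal_nt = 114L, max_gap_frac = 0.5) {
  stats_ <- map(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    ep <- r$ext_pos[[1]]
    n <- length(ep)
    cov <- left_join(tibble(chrom = r$chrom, strand = r$strand, pos = ep),
                     fp_track, by = c("chrom", "strand", "pos"))
    w <- dplyr::coalesce(cov$weight, 0)
    covered <- which(w > 1e-12)
    dp <- r$distal_pos[[1]][seq_len(min(distal_nt, length(r$distal_pos[[1]])))]
    distal_rpkm <- region_count(
      fp_track, tibble(chrom = r$chrom, strand = r$strand, pos = dp)) /
      (length(dp) / 1000) / (library_size / 1e6)
    peak_w <- region_count(
      fp_track, tibble(chrom = r$chrom, strand = r$strand,
                       pos = r$ext_stop_codon_pos[[1]]))
    gaps <- diff(c(0L, covered, n + 1L)) - 1L
    tibble(
      cov_frac = length(covered) / n,
      first_frac = if (length(covered)) covered[1] / n else NA_real_,
      last_frac = if (length(covered)) covered[length(covered)] / n
                  else NA_real_,
      max_gap_frac_obs = if (n > 0) max(gaps) / n else NA_real_,
      distal_rpkm = distal_rpkm,
      drop_fraction = if (!is.na(r$ext_rpkm) && r$ext_rpkm > 0) {
        1 - distal_rpkm / r$ext_rpkm
      } else NA_real_,
      stop_peak_weight = peak_w
    )
  }) |> bind_rows()
  out <- bind_cols(records, stats_)
  mutate(out,
    filter_a = !is.na(.data$ext_rpkm) & .data$ext_rpkm >= min_ext_rpkm,
    filter_b = !is.na(.data$rho) & .data$rho >= min_rho,
    filter_c = .data$cov_frac >= min_coverage,
    filter_d = !is.na(.data$first_frac) & .data$first_frac <= 0.25,
    filter_e = !is.na(.data$last_frac) & .data$last_frac >= 0.75,
    filter_f = !is.na(.data$drop_fraction) & .data$drop_fraction >= min_drop,
    even_spaced = !is.na(.data$max_gap_frac_obs) &
      .data$max_gap_frac_obs <= max_gap_frac
  )
}

#' Score candidates as readthrough / ambiguous / negative
#'
#' Automated operationalisation of the manual scoring rules: a candidate
#' scores `readthrough` when density exists in the extension (a), the rate
#' floor holds (b), density drops sharply after the extension's stop (f),
#' and the extension is evenly covered (c, d, e and the maximum-gap
#' criterion). When coverage is sparse the evenness requirement is relaxed
#' if the extension's stop codon carries a peak of at least
#' `min_stop_peak` reads. Candidates with no credible density (failing a
#' or b) or failing two or more coverage criteria score `negative`;
#' borderline cases score `ambiguous`.
#'
#' @param records Filtered record tibble from [apply_filters()].
#' @param min_stop_peak Sparse-relaxation peak weight, default 2 reads.
#' @return `records` with `score` and `reasons` columns.
#' @export
score_candidates <- function(records, min_stop_peak = 2) {
  flags <- c("filter_c", "filter_d", "filter_e", "even_spaced")
  res <- map(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    fails <- flags[!map_lgl(flags, function(f) isTRUE(r[[f]]))]
    core <- isTRUE(r$filter_a) && isTRUE(r$filter_b) && isTRUE(r$filter_f)
    if (!isTRUE(r$testable)) {
      tibble(score = "untestable", reasons = "CDS below count threshold")
    } else if (core && length(fails) == 0) {
      tibble(score = "readthrough", reasons = "")
    } else if (core && r$stop_peak_weight >= min_stop_peak) {
      tibble(score = "readthrough", reasons = "sparse; stop codon peak")
    } else if (!isTRUE(r$filter_a) || !isTRUE(r$filter_b)) {
      tibble(score = "negative",
             reasons = paste(c("filter_a", "filter_b")[
               !c(isTRUE(r$filter_a), isTRUE(r$filter_b))], collapse = ","))
    } else if (length(fails) >= 2 || !isTRUE(r$filter_f)) {
      tibble(score = "negative",
             reasons = paste(c(fails, if (!isTRUE(r$filter_f)) "filter_f"),
                             collapse = ","))
    } else {
      tibble(score = "ambiguous", reasons = paste(fails, collapse = ","))
    }
  }) |> bind_rows()
  bind_cols(records, res)
}

#' Detect readthrough events
#'
#' Pipeline wrapper: quantifies candidates, applies filters, scores them,
#' and keeps second-tier (double readthrough) candidates only when the
#' first-tier candidate at the same stop scored positive.
#'
#' @inheritParams readthrough_rate
#' @inheritParams apply_filters
#' @param ... Passed to [apply_filters()].
#' @return Scored record tibble.
#' @export
detect_readthrough <- function(candidates, annotation, fp_track,
                               library_size, min_cds_reads = 128,
                               extra_mask = NULL, ...) {
  if (nrow(candidates) == 0) return(candidates)
  recs <- readthrough_rate(candidates, annotation, fp_track, library_size,
                           min_cds_reads = min_cds_reads,
                           extra_mask = extra_mask) |>
    apply_filters(fp_track, library_size, ...) |>
    score_candidates()
  pos1 <- recs$gene_id[recs$tier == 1 & recs$score == "readthrough"]
  filter(recs, .data$tier == 1 |
           (.data$tier == 2 & .data$gene_id %in% pos1))
}

#' Differential readthrough between two samples
#'
#' For genes whose isoforms covering the extension share one CDS, whose
#' CDS has at least `min_cds_reads` footprints in both samples, and whose
#' extension scored positive in either, builds the 2x2 table of
#' peak-masked (CDS, extension) footprint counts in the two samples,
#' tests it with the two-sided exact Fisher test, controls FDR by
#' Benjamini-Hochberg at `alpha`, and reports the log10 fold change of the
#' readthrough rate (sample 2 over sample 1).
#'
#' @param records1,records2 Scored record tibbles from
#'   [detect_readthrough()] for the two samples.
#' @param min_cds_reads CDS count floor per sample, default 128.
#' @param alpha FDR level, default 0.05.
#' @return Tibble with counts, `p`, `q`, `significant`, `log10_fold` and
#'   `direction`, plus an `ineligible` attribute naming excluded
#'   candidates and reasons.
#' @export
differential_readthrough <- function(records1, records2,
                                     min_cds_reads = 128, alpha = 0.05) {
  j <- inner_join(
    select(filter(records1, .data$tier == 1), "candidate_id", "gene_id",
           "same_cds", "cds_count", "ext_count", "rho", "score"),
    select(filter(records2, .data$tier == 1), "candidate_id", "cds_count",
           "ext_count", "rho", "score"),
    by = "candidate_id", suffix = c("_1", "_2")
  )
  elig <- mutate(j,
    reason = dplyr::case_when(
      !same_cds ~ "isoforms differ in CDS",
      cds_count_1 < min_cds_reads | cds_count_2 < min_cds_reads ~
        "CDS below count threshold",
      score_1 != "readthrough" & score_2 != "readthrough" ~
        "not scored positive in either sample",
      TRUE ~ ""
    )
  )
  ineligible <- filter(elig, .data$reason != "")
  ok <- filter(elig, .data$reason == "")
  if (nrow(ok) == 0) {
    out <- tibble(candidate_id = character(0))
    attr(out, "ineligible") <- select(ineligible, "candidate_id", "reason")
    return(out)
  }
  ok$p <- map_dbl(seq_len(nrow(ok)), function(i) {
    fisher_exact(matrix(round(c(ok$cds_count_1[i], ok$ext_count_1[i],
                                ok$cds_count_2[i], ok$ext_count_2[i])),
                        nrow = 2, byrow = TRUE))
  })
  adj <- bh_fdr(ok$p, alpha = alpha)
  out <- ok |>
    mutate(
      q = adj$q, significant = adj$rejected,
      log10_fold = log10(.data$rho_2 / .data$rho_1),
      direction = if_else(.data$log10_fold > 0, "up", "down")
    ) |>
    select(-"reason") |>
    arrange(.data$p)
  attr(out, "ineligible") <- select(ineligible, "candidate_id", "reason")
  out
}
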