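# Per-position mismatch statistics over stop codons: exclude genomic
# polymorphism and A-to-I editing explanations for apparent readthrough.

#' Stop codon nucleotide positions
#'
#' One row per (unique annotated stop codon, codon offset 1-3) with the
#' genomic position and reference base in mRNA sense.
#'
#' @param annotation Exon-level annotation tibble.
#' @param genome Named character vector of chromosome sequences.
#' @return Tibble with `stop_id`, `offset`, `chrom`, `strand`, `pos`,
#'   `ref`.
#' @export
stop_codon_positions <- function(annotation, genome) {
  txs <- split_transcripts(annotation)
  rows <- bind_rows(map(txs, function(tx) {
    if (is.na(tx$cds_stop[1])) return(NULL)
    pos <- tx_positions(tx)
    b <- tx_cds_bounds(tx)
    gpos <- pos[(b[["stop"]] + 1L):(b[["stop"]] + 3L)]
    seq_ <- tx_sequence(genome, tx)
    tibble(
      stop_id = paste0(tx$chrom[1], ":", gpos[1], "(", tx$strand[1], ")"),
      offset = 1:3, chrom = tx$chrom[1], strand = tx$strand[1], pos = gpos,
      ref = str_split(str_sub(seq_, b[["stop"]] + 1L, b[["stop"]] + 3L),
                      "")[[1]]
    )
  }))
  distinct(rows, .data$stop_id, .data$offset, .keep_all = TRUE)
}

parse_mm <- function(mm) {
  if (is.na(mm)) return(NULL)
  parts <- str_match_all(mm, "(\\d+):([ACGT])>([ACGT])")[[1]]
  tibble(off = as.integer(parts[, 2]), ref = parts[, 3], alt = parts[, 4])
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Tabulate matching and mismatching reads over stop codon positions
#'
#' For each stop codon nucleotide, counts reads whose alignment covers the
#' position with a matching base (m) or a mismatching base (x, by
#' substitution class, reported in mRNA sense). The first aligned base of
#' each read (5' end in read orientation) is excluded from both tallies,
#' as such mismatches commonly arise from non-templated addition by
#' reverse transcriptase. Three datasets are supported: mRNA fragments,
#' all footprints, and the subset of footprints whose P-sites have passed
#' the position (ribosomes that have already translated it).
#'
#' @param alignments Alignment tibble (with `mm` mismatch strings).
#' @param stops Stop-codon position tibble from [stop_codon_positions()].
#' @param dataset `"mrna"`, `"footprints_all"` or `"footprints_Apassed"`.
#' @return MismatchTable tibble: `stop_id`, `offset`, `pos`, `ref`, `m`,
#'   `x`, `classes` (list of named counts), `dataset`.
#' @export
tabulate_mismatches <- function(alignments, stops,
                                dataset = c("mrna", "footprints_all",
                                            "footprints_Apassed")) {
  dataset <- match.arg(dataset)
  aln <- alignments
  if (dataset != "mrna") aln <- filter(aln, .data$len >= MIN_FOOTPRINT)
  out <- map(seq_len(nrow(stops)), function(i) {
    st <- stops[i, ]
    cover <- filter(aln, .data$chrom == st$chrom,
                    .data$pos <= st$pos, .data$pos + .data$len > st$pos)
    if (dataset == "footprints_Apassed") {
      cover <- if (st$strand == "+") {
        filter(cover, .data$pos + PSITE_TRIM > st$pos)
      } else {
        filter(cover, .data$pos + .data$len - 1L - PSITE_TRIM < st$pos)
      }
    }
    first_base <- if_else(cover$strand == "+", cover$pos,
                          cover$pos + cover$len - 1L)
    cover <- cover[first_base != st$pos, ]
    x_classes <- integer(0)
    n_x <- 0L
    if (nrow(cover) > 0) {
      with_mm <- which(!is.na(cover$mm))
      for (k in with_mm) {
        mmk <- parse_mm(cover$mm[k])
        hit <- mmk[cover$pos[k] + mmk$off == st$pos, ]
        if (nrow(hit) > 0) {
          ref <- hit$ref[1]; alt <- hit$alt[1]
          if (st$strand == "-") {
            ref <- COMPLEMENT[[ref]]; alt <- COMPLEMENT[[alt]]
          }
          cls <- paste0(ref, ">", alt)
          x_classes[cls] <- (if (cls %in% names(x_classes))
            x_classes[[cls]] else 0L) + 1L
          n_x <- n_x + 1L
        }
      }
    }
    tibble(stop_id = st$stop_id, offset = st$offset, chrom = st$chrom,
           strand = st$strand, pos = st$pos, ref = st$ref,
           m = nrow(cover) - n_x, x = n_x,
           classes = list(x_classes), dataset = dataset)
  })
  bind_rows(out)
}

#' Test stop codon positions for elevated mismatch rates
#'
#' Computes a global average mismatch frequency for each codon offset
#' (first, second, third base) across all positions in the dataset, then
#' tests each position's mismatch count against its offset's global rate
#' with a one-sided (greater) exact binomial test, controlling FDR at
#' `alpha` by Benjamini-Hochberg. Positions with zero coverage are
#' flagged untested.
#'
#' @param table MismatchTable from [tabulate_mismatches()].
#' @param alpha FDR level, default 0.05.
#' @return `table` with `n`, `global_rate`, `tested`, `p`, `q`,
#'   `significant` added.
#' @export
elevated_mismatch_test <- function(table, alpha = 0.05) {
  tab <- mutate(table, n = .data$m + .data$x)
  glob <- tab |>
    group_by(.data$offset) |>
    summarise(global_rate = sum(.data$x) / max(1, sum(.data$n)),
              .groups = "drop")
  tab <- left_join(tab, glob, by = "offset") |>
    mutate(tested = .data$n > 0)
  tab$p <- NA_real_
  idx <- which(tab$tested)
  tab$p[idx] <- map_dbl(idx, function(i) {
    binomial_tail(tab$x[i], tab$n[i], tab$global_rate[i], "greater")
  })
  adj <- bh_fdr(tab$p, alpha = alpha)
  tab$q <- adj$q
  tab$significant <- adj$rejected
  tab
}

#' Classify significant mismatch calls
#'
#' Positions whose dominant substitution class accounts for roughly 50%
#' (heterozygous band) or at least 90% (homozygous) of covering reads are
#' called genomic polymorphisms, subdivided by whether the mutated codon
#' remains a stop (`stop_to_stop_polymorphism`) or becomes sense
#' (`stop_to_sense_polymorphism`; the transcript is flagged for
#' exclusion). Among the rest, a position is an `editing_candidate` only
#' when the reference base is adenine and the dominant class is A>G (the
#' A-to-I signature); anything else is `sequencing_error`.
#'
#' @param calls Output of [elevated_mismatch_test()].
#' @param stops Stop-codon position tibble (for codon context).
#' @param het_band Heterozygous allele-fraction band, default
#'   `c(0.35, 0.65)`.
#' @param hom_min Homozygous allele-fraction floor, default 0.9.
#' @return Significant calls with `classification`, `dominant_class`,
#'   `allele_fraction` and `exclude_transcript`.
#' @export
classify_calls <- function(calls, stops, het_band = c(0.35, 0.65),
                           hom_min = 0.9) {
  codons <- stops |>
    arrange(.data$stop_id, .data$offset) |>
    group_by(.data$stop_id) |>
    summarise(codon = paste(.data$ref, collapse = ""), .groups = "drop")
  sig <- filter(calls, .data$significant)
  res <- map(seq_len(nrow(sig)), function(i) {
    r <- sig[i, ]
    cls <- r$classes[[1]]
    dom <- names(cls)[which.max(cls)]
    f <- cls[[dom]] / r$n
    alt <- str_sub(dom, 3, 3)
    codon <- codons$codon[codons$stop_id == r$stop_id]
    mutated <- codon
    str_sub(mutated, r$offset, r$offset) <- alt
    is_poly <- f >= hom_min || (f >= het_band[1] && f <= het_band[2])
    classification <- if (is_poly) {
      if (mutated %in% STOP_CODONS) "stop_to_stop_polymorphism"
      else "stop_to_sense_polymorphism"
    } else if (r$ref == "A" && dom == "A>G") {
      "editing_candidate"
    } else {
      "sequencing_error"
    }
    tibble(classification = classification, dominant_class = dom,
           allele_fraction = f,
           exclude_transcript = classification == "stop_to_sense_polymorphism")
  })
  bind_cols(sig, bind_rows(res))
}

#' Positive-evidence test against A-to-I editing
#'
#' Under the null that editing drives readthrough, nearly all footprints
#' from ribosomes that have passed the stop codon should carry an edited
#' base; conservatively assuming a `null_fraction` (default 90%) edited
#' proportion, each sufficiently covered adenine position is tested for a
#' significantly *lower* observed A>G proportion with a one-sided exact
#' binomial test, Bonferroni-corrected over tested positions. A
#' significant result is positive evidence against editing at that
#' position.
#'
#' @param table A-site-passed MismatchTable from [tabulate_mismatches()].
#' @param null_fraction Assumed edited proportion under the null,
#'   default 0.9.
#' @param alpha Family-wise level, default 0.05.
#' @return Tibble of tested adenine positions with `k_ag`, `n`, `p`,
#'   `p_bonferroni` and `editing_rejected`.
#' @export
editing_null_test <- function(table, null_fraction = 0.9, alpha = 0.05) {
  tab <- mutate(table, n = .data$m + .data$x)
  aden <- filter(tab, .data$ref == "A", .data$n > 0)
  if (nrow(aden) == 0) return(tibble(stop_id = character(0)))
  aden$k_ag <- map_int(aden$classes, function(cl) {
    if ("A>G" %in% names(cl)) cl[["A>G"]] else 0L
  })
  aden$p <- map_dbl(seq_len(nrow(aden)), function(i) {
    binomial_tail(aden$k_ag[i], aden$n[i], null_fraction, "less")
  })
  aden$p_bonferroni <- pmin(1, aden$p * nrow(aden))
  aden$editing_rejected <- aden$p_bonferroni < alpha
  select(aden, "stop_id", "offset", "chrom", "strand", "pos", "ref",
         "k_ag", "n", "p", "p_bonferroni", "editing_rejected")
}
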