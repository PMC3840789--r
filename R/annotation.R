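# Countable coordinate space: degeneracy masking, locus merging, region
# labelling.

#' Flag degenerate (multi-mapping) genomic positions
#'
#' A position is degenerate when the k-mer centred on it (position +/- 14 nt
#' for the default 29-mer) occurs elsewhere in the genome with zero
#' mismatches, optionally counting reverse-complement occurrences, so that
#' reads arising from it cannot be mapped uniquely. Positions too close to a
#' sequence end to form a centred window are flagged unmappable and treated
#' as degenerate downstream.
#'
#' @param genome Named character vector (or list) of chromosome sequences.
#' @param k Window size, default 29 (must be odd).
#' @param both_strands Count reverse-complement occurrences too (default
#'   TRUE; aligners map both strands).
#' @return Tibble with `chrom`, `pos` (0-based) and `reason`
#'   (`"degenerate"` or `"unmappable"`).
#' @export
mask_degenerate_positions <- function(genome, k = 29L, both_strands = TRUE) {
  if (length(genome) == 0 || any(nchar(unlist(genome)) == 0)) {
    stop("genome must be non-empty")
  }
  if (k %% 2L != 1L) stop("k must be odd")
  half <- (k - 1L) %/% 2L
  chroms <- names(genome)
  per_chrom <- map(chroms, function(ch) {
    seq_ <- str_to_upper(genome[[ch]])
    len <- nchar(seq_)
    centers <- seq.int(half, len - half - 1L)   # 0-based centre positions
    if (length(centers) == 0 || centers[1] > centers[length(centers)]) {
      centers <- integer(0)
    }
    kmers <- if (length(centers) > 0) {
      str_sub(seq_, centers - half + 1L, centers + half + 1L)
    } else character(0)
    edge <- setdiff(seq.int(0L, len - 1L), centers)
    list(chrom = ch, centers = centers, kmers = kmers, edge = edge)
  })
  all_kmers <- unlist(map(per_chrom, "kmers"), use.names = FALSE)
  key <- if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(all_kmers)))
    pmin(all_kmers, rc)
  } else {
    all_kmers
  }
  counts <- table(key)
  degen <- counts[key] > 1L
  offset <- 0L
  out <- map(per_chrom, function(pc) {
    n <- length(pc$kmers)
    idx <- if (n > 0) seq.int(offset + 1L, offset + n) else integer(0)
    offset <<- offset + n
    bind_rows(
      tibble(chrom = pc$chrom, pos = pc$centers[degen[idx]],
             reason = "degenerate"),
      tibble(chrom = pc$chrom, pos = pc$edge, reason = "unmappable")
    )
  })
  arrange(bind_rows(out), .data$chrom, .data$pos)
}

#' Merge genes whose transcripts share exons
#'
#' Genes are merged into loci by transitive closure of same-strand exon
#' overlap (polycistronic annotations, shared exons). Opposite-strand
#' overlap does not merge genes.
#'
#' @param annotation Exon-level annotation tibble.
#' @return Tibble mapping `locus_id` to `gene_id`.
#' @export
merge_loci <- function(annotation) {
  validate_annotation(annotation)
  genes <- unique(annotation$gene_id)
  parent <- seq_along(genes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  ex <- annotation
  keys <- split(seq_len(nrow(ex)), paste(ex$chrom, ex$strand))
  for (idx in keys) {
    e <- ex[idx, ]
    gi <- match(e$gene_id, genes)
    if (length(idx) < 2) next
    ord <- order(e$start)
    for (a in seq_len(length(ord) - 1L)) {
      for (b in seq.int(a + 1L, length(ord))) {
        ia <- ord[a]; ib <- ord[b]
        if (e$start[ib] >= e$end[ia]) break
        if (gi[ia] != gi[ib]) union_(gi[ia], gi[ib])
      }
    }
  }
  roots <- map_int(seq_along(genes), find)
  locus <- match(roots, sort(unique(roots)))
  tibble(locus_id = sprintf("locus_%03d", locus), gene_id = genes) |>
    arrange(.data$locus_id, .data$gene_id)
}

#' Exonic positions of each merged locus
#'
#' Unions the exonic positions of every transcript in a locus and removes
#' any genomic position attributed to two or more loci (such positions are
#' excluded from all loci).
#'
#' @param annotation Exon-level annotation tibble.
#' @param loci Locus membership from [merge_loci()]; computed if omitted.
#' @return Tibble with `locus_id`, `chrom`, `strand`, `pos`.
#' @export
locus_positions <- function(annotation, loci = merge_loci(annotation)) {
  txs <- split_transcripts(annotation)
  pos <- bind_rows(map(txs, function(tx) {
    tibble(gene_id = tx$gene_id[1], chrom = tx$chrom[1],
           strand = tx$strand[1], pos = sort(tx_positions(tx)))
  }))
  pos <- distinct(left_join(pos, loci, by = "gene_id"),
                  .data$locus_id, .data$chrom, .data$strand, .data$pos)
  multi <- pos |>
    distinct(.data$locus_id, .data$chrom, .data$pos) |>
    count(.data$chrom, .data$pos) |>
    filter(.data$n > 1)
  anti_join(pos, multi, by = c("chrom", "pos")) |>
    arrange(.data$locus_id, .data$chrom, .data$pos)
}

#' Label locus positions by transcript region
#'
#' A position is labelled `5UTR`, `CDS` (stop codon included) or `3UTR` only
#' if every transcript isoform containing it agrees; positions on which
#' isoforms disagree are labelled `ambiguous` (still exonic, but excluded
#' from region-specific analyses). Labels are independent of transcript
#' input order.
#'
#' @param positions Locus position tibble from [locus_positions()].
#' @param annotation Exon-level annotation tibble.
#' @return `positions` with a `label` column added.
#' @export
label_regions <- function(positions, annotation) {
  txs <- split_transcripts(annotation)
  per_tx <- bind_rows(map(txs, function(tx) {
    lab <- tx_region_labels(tx)
    lab$gene_id <- tx$gene_id[1]
    lab
  }))
  agreed <- per_tx |>
    distinct(.data$chrom, .data$strand, .data$pos, .data$label) |>
    group_by(.data$chrom, .data$strand, .data$pos) |>
    summarise(label = if (n() == 1) .data$label[1] else "ambiguous",
              .groups = "drop")
  left_join(positions, agreed, by = c("chrom", "strand", "pos"))
}

#' Fraction of degenerate positions per locus
#'
#' @param positions Locus position tibble (from [locus_positions()]).
#' @param degenerate Degenerate-position tibble from
#'   [mask_degenerate_positions()].
#' @return Tibble with `locus_id`, `n_exonic`, `n_degenerate`,
#'   `fraction_degenerate`.
#' @export
fraction_degenerate <- function(positions, degenerate) {
  marked <- mark_degenerate(positions, degenerate)
  marked |>
    group_by(.data$locus_id) |>
    summarise(n_exonic = n(), n_degenerate = sum(.data$degenerate),
              fraction_degenerate = .data$n_degenerate / .data$n_exonic,
              .groups = "drop")
}

mark_degenerate <- function(positions, degenerate) {
  key <- paste(degenerate$chrom, degenerate$pos)
  mutate(positions, degenerate = paste(.data$chrom, .data$pos) %in% key)
}

#' Countable-locus filter
#'
#' A locus is countable when at least `min_nondegenerate` of its exonic
#' positions are non-degenerate, its exonic length after excluding
#' degenerate and multi-locus positions is at least `min_length`, and none
#' of its genes carries an excluded biotype (abundant non-translated RNAs).
#'
#' @param positions Locus position tibble.
#' @param annotation Exon-level annotation (for biotypes; a missing
#'   `biotype` column counts every gene as protein coding).
#' @param degenerate Degenerate-position tibble.
#' @param min_nondegenerate Minimum non-degenerate fraction, default 0.95.
#' @param min_length Minimum exonic length after exclusions, default 60 nt.
#' @param excluded_biotypes Biotypes whose loci are dropped.
#' @return Locus summary tibble with a `countable` flag.
#' @export
countable_loci <- function(positions, annotation, degenerate,
                           min_nondegenerate = 0.95, min_length = 60L,
                           excluded_biotypes = c("miRNA", "pre_miRNA",
                                                 "rRNA", "snRNA", "snoRNA",
                                                 "tRNA")) {
  frac <- fraction_degenerate(positions, degenerate)
  loci <- merge_loci(annotation)
  bio <- if ("biotype" %in% names(annotation)) {
    distinct(annotation, .data$gene_id, .data$biotype)
  } else {
    tibble(gene_id = unique(annotation$gene_id), biotype = "protein_coding")
  }
  excluded <- loci |>
    left_join(bio, by = "gene_id") |>
    group_by(.data$locus_id) |>
    summarise(excluded_biotype = any(.data$biotype %in% excluded_biotypes),
              .groups = "drop")
  frac |>
    left_join(excluded, by = "locus_id") |>
    mutate(
      usable_length = .data$n_exonic - .data$n_degenerate,
      countable = (1 - .data$fraction_degenerate) >= min_nondegenerate &
        .data$usable_length >= min_length & !.data$excluded_biotype
    )
}
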