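# Transcript-model helpers. An annotation is a tibble with one row per exon:
# gene_id, transcript_id, chrom, strand, start, end (0-based half-open),
# cds_start, cds_stop (genomic coordinate of the first CDS base and of the
# first base of the stop codon, repeated on every exon row of a transcript),
# biotype.

#' Validate an exon-level annotation table
#'
#' Checks the structural invariants of transcript models: required columns,
#' non-overlapping sorted exons, CDS contained in the exons, and a CDS length
#' (stop codon included) divisible by three.
#'
#' @param annotation Exon-level annotation tibble.
#' @return The annotation, invisibly, if valid; otherwise an error.
#' @export
validate_annotation <- function(annotation) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end",
            "cds_start", "cds_stop")
  miss <- setdiff(need, names(annotation))
  if (length(miss) > 0) {
    stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  }
  if (!all(annotation$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  by_tx <- split(annotation, annotation$transcript_id)
  for (tx in by_tx) {
    ex <- tx[order(tx$start), ]
    if (any(ex$end <= ex$start)) stop("empty exon in ", ex$transcript_id[1])
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("overlapping exons in ", ex$transcript_id[1])
    }
    if (!is.na(ex$cds_start[1])) {
      pos <- tx_positions(ex)
      s <- match(ex$cds_start[1], pos)
      t <- match(ex$cds_stop[1], pos)
      if (is.na(s) || is.na(t)) {
        stop("CDS boundaries outside exons in ", ex$transcript_id[1])
      }
      if (t <= s) stop("malformed CDS in ", ex$transcript_id[1])
      if ((t + 3L - s) %% 3L != 0L) {
        stop("CDS length not divisible by 3 in ", ex$transcript_id[1])
      }
    }
  }
  invisible(annotation)
}

# Genomic positions of one transcript, 5'->3' in transcript orientation.
tx_positions <- function(tx_exons) {
  ex <- tx_exons[order(tx_exons$start), ]
  pos <- unlist(map2(ex$start, ex$end, function(s, e) seq.int(s, e - 1L)),
                use.names = FALSE)
  if (ex$strand[1] == "-") rev(pos) else pos
}

# Spliced transcript sequence in mRNA sense.
tx_sequence <- function(genome, tx_exons) {
  ex <- tx_exons[order(tx_exons$start), ]
  chrom_seq <- genome[[ex$chrom[1]]]
  parts <- str_sub(chrom_seq, ex$start + 1L, ex$end)
  s <- paste(parts, collapse = "")
  if (ex$strand[1] == "-") revcomp(s) else s
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Transcript coordinates (0-based, 5'->3') of cds_start and of the first
# base of the stop codon.
tx_cds_bounds <- function(tx_exons) {
  pos <- tx_positions(tx_exons)
  c(cds = match(tx_exons$cds_start[1], pos) - 1L,
    stop = match(tx_exons$cds_stop[1], pos) - 1L)
}

# Region label of each transcript position: 5UTR / CDS (stop codon
# included) / 3UTR.
tx_region_labels <- function(tx_exons) {
  pos <- tx_positions(tx_exons)
  b <- tx_cds_bounds(tx_exons)
  lab <- rep("3UTR", length(pos))
  lab[seq_along(pos) - 1L < b["cds"]] <- "5UTR"
  idx <- seq_along(pos) - 1L
  lab[idx >= b["cds"] & idx <= b["stop"] + 2L] <- "CDS"
  tibble(chrom = tx_exons$chrom[1], strand = tx_exons$strand[1],
         pos = pos, tx_offset = idx, label = lab)
}

# Split an annotation into per-transcript exon tables.
split_transcripts <- function(annotation) {
  split(annotation, annotation$transcript_id)
}

#' Format extension coordinates with splice-junction notation
#'
#' Renders a set of 5'->3' genomic positions as `chrom:start-end(strand)`,
#' joining discontiguous blocks with `^`. Coordinates are 0-based half-open.
#'
#' @param chrom Chromosome name.
#' @param positions Integer vector of genomic positions (0-based).
#' @param strand `"+"` or `"-"`.
#' @return A single string.
#' @export
format_region_coords <- function(chrom, positions, strand) {
  p <- sort(unique(positions))
  brk <- c(0L, which(diff(p) != 1L), length(p))
  blocks <- map_chr(seq_len(length(brk) - 1L), function(i) {
    seg <- p[(brk[i] + 1L):brk[i + 1L]]
    paste0(seg[1], "-", seg[length(seg)] + 1L)
  })
  paste0(chrom, ":", paste(blocks, collapse = "^"), "(", strand, ")")
}
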