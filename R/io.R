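# Format boundaries. Internals are 0-based half-open; GFF3 (1-based
# closed) and SAM (1-based) are converted here. Standard parsers/writers
# (Biostrings, rtracklayer, Rsamtools) do the heavy lifting; the SAM
# *writer* is minimal by design so simulated alignments flow through the
# same ingestion path as real data.

#' Read / write a genome as FASTA
#'
#' @param path FASTA file.
#' @param genome Named character vector of chromosome sequences.
#' @return `read_genome_fasta` returns a named character vector.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(genome)), path)
  invisible(path)
}

#' Write an annotation as GFF3
#'
#' Emits mRNA, exon and CDS features per transcript (CDS includes the stop
#' codon, 1-based closed coordinates per the GFF3 specification) with ID,
#' Parent and biotype attributes.
#'
#' @param annotation Exon-level annotation tibble.
#' @param path Output file.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  txs <- split_transcripts(annotation)
  feats <- bind_rows(map(txs, function(tx) {
    ex <- tx[order(tx$start), ]
    rows <- list(tibble(
      chrom = ex$chrom[1], start = min(ex$start), end = max(ex$end),
      strand = ex$strand[1], type = "mRNA", ID = ex$transcript_id[1],
      Parent = ex$gene_id[1],
      biotype = if ("biotype" %in% names(ex)) ex$biotype[1] else
        "protein_coding"
    ))
    rows$exon <- tibble(
      chrom = ex$chrom, start = ex$start, end = ex$end, strand = ex$strand,
      type = "exon", ID = paste0(ex$transcript_id, ".e", seq_len(nrow(ex))),
      Parent = ex$transcript_id, biotype = NA_character_
    )
    if (!is.na(ex$cds_start[1])) {
      pos <- tx_positions(ex)
      b <- tx_cds_bounds(ex)
      cpos <- sort(pos[(b[["cds"]] + 1L):(b[["stop"]] + 3L)])
      brk <- c(0L, which(diff(cpos) != 1L), length(cpos))
      segs <- bind_rows(map(seq_len(length(brk) - 1L), function(i) {
        seg <- cpos[(brk[i] + 1L):brk[i + 1L]]
        tibble(chrom = ex$chrom[1], start = seg[1],
               end = seg[length(seg)] + 1L, strand = ex$strand[1],
               type = "CDS", ID = paste0(ex$transcript_id[1], ".cds"),
               Parent = ex$transcript_id[1], biotype = NA_character_)
      }))
      # GFF3 phase: bases to skip to reach the next codon start, in
      # translation order
      ord <- if (ex$strand[1] == "-") order(-segs$start) else
        order(segs$start)
      cum <- cumsum(c(0L, (segs$end - segs$start)[ord]))
      segs$phase <- NA_integer_
      segs$phase[ord] <- (3L - cum[seq_len(nrow(segs))] %% 3L) %% 3L
      rows$cds <- segs
    }
    bind_rows(rows)
  }))
  if (!"phase" %in% names(feats)) feats$phase <- NA_integer_
  gr <- GenomicRanges::GRanges(
    feats$chrom, IRanges::IRanges(feats$start + 1L, feats$end),
    strand = feats$strand, type = feats$type, ID = feats$ID,
    Parent = feats$Parent, biotype = feats$biotype,
    phase = feats$phase
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation into the exon-level tibble
#'
#' @param path GFF3 file written by [write_annotation_gff3()] or
#'   structurally equivalent (mRNA/exon/CDS with ID and Parent).
#' @return Exon-level annotation tibble.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  d <- as_tibble(as.data.frame(gr))
  d$Parent <- map_chr(d$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  })
  mrna <- filter(d, .data$type == "mRNA")
  exons <- filter(d, .data$type == "exon")
  cds <- filter(d, .data$type == "CDS")
  out <- map(seq_len(nrow(mrna)), function(i) {
    txid <- mrna$ID[i]
    ex <- filter(exons, .data$Parent == txid) |> arrange(.data$start)
    cd <- filter(cds, .data$Parent == txid)
    tab <- tibble(
      gene_id = mrna$Parent[i], transcript_id = txid,
      chrom = as.character(ex$seqnames), strand = as.character(ex$strand),
      start = ex$start - 1L, end = ex$end,
      cds_start = NA_integer_, cds_stop = NA_integer_,
      biotype = mrna$biotype[i] %||% "protein_coding"
    )
    if (nrow(cd) > 0) {
      cpos <- sort(unlist(map2(cd$start - 1L, cd$end,
                               function(s, e) seq.int(s, e - 1L))))
      ordered <- if (tab$strand[1] == "-") rev(cpos) else cpos
      tab$cds_start <- ordered[1]
      tab$cds_stop <- ordered[length(ordered) - 2L]
    }
    tab
  })
  bind_rows(out)
}

sam_seq <- function(genome, read) {
  s <- str_sub(genome[[read$chrom]], read$pos + 1L, read$pos + read$len)
  if (!is.na(read$mm)) {
    mmk <- parse_mm(read$mm)
    for (i in seq_len(nrow(mmk))) {
      str_sub(s, mmk$off[i] + 1L, mmk$off[i] + 1L) <- mmk$alt[i]
    }
  }
  s
}

sam_md <- function(read) {
  if (is.na(read$mm)) return(as.character(read$len))
  mmk <- parse_mm(read$mm) |> arrange(.data$off)
  runs <- diff(c(-1L, mmk$off)) - 1L
  paste0(paste0(runs, mmk$ref, collapse = ""),
         read$len - mmk$off[nrow(mmk)] - 1L)
}

#' Write alignments as minimal SAM
#'
#' QNAME/FLAG/RNAME/POS/CIGAR (pure matches) plus SEQ reconstructed from
#' the genome with mismatches applied, and MD/NM tags describing the
#' mismatches, so that the ingestion path for simulated data matches real
#' data.
#'
#' @param alignments Alignment tibble.
#' @param genome Named character vector of chromosome sequences.
#' @param path Output `.sam` path.
#' @export
write_sam <- function(alignments, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   nchar(unlist(genome))))
  body <- map_chr(seq_len(nrow(alignments)), function(i) {
    r <- alignments[i, ]
    seq_ <- sam_seq(genome, r)  # SAM stores SEQ in reference orientation
    nm <- if (is.na(r$mm)) 0L else nrow(parse_mm(r$mm))
    paste(r$qname, if (r$strand == "-") 16L else 0L, r$chrom, r$pos + 1L,
          255L, paste0(r$len, "M"), "*", 0L, 0L, seq_,
          "*", paste0("MD:Z:", sam_md(r)), paste0("NM:i:", nm),
          sep = "\t")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignments from SAM/BAM
#'
#' Uses Rsamtools (SAM input is converted to BAM first). Only
#' ungapped (`<n>M`) alignments are supported; mismatches are
#' reconstructed from the MD tag and the stored sequence into the
#' package's `off:REF>ALT` notation (genomic orientation).
#'
#' @param path `.sam` or `.bam` file.
#' @return Alignment tibble (`qname`, `chrom`, `strand`, `pos`, `len`,
#'   `mm`).
#' @export
read_alignments <- function(path) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else {
    path
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "seq", "cigar"),
    tag = "MD")
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (!all(grepl("^\\d+M$", res$cigar))) {
    stop("only ungapped (nM) alignments are supported")
  }
  md <- res$tag$MD
  seqs <- as.character(res$seq)
  mm <- map_chr(seq_along(md), function(i) {
    toks <- str_match_all(md[i], "(\\d+)|([A-Z])")[[1]]
    off <- -1L
    recs <- character(0)
    aligned <- seqs[i]  # stored SEQ is already reference-oriented
    for (r in seq_len(nrow(toks))) {
      if (!is.na(toks[r, 2]) && toks[r, 2] != "") {
        off <- off + as.integer(toks[r, 2])
      } else {
        off <- off + 1L
        recs <- c(recs, paste0(off, ":", toks[r, 3], ">",
                               str_sub(aligned, off + 1L, off + 1L)))
      }
    }
    if (length(recs) == 0) NA_character_ else paste(recs, collapse = ",")
  })
  tibble(
    qname = res$qname,
    chrom = as.character(res$rname),
    strand = if_else(bitwAnd(res$flag, 16L) > 0, "-", "+"),
    pos = res$pos - 1L, len = res$qwidth, mm = mm
  )
}

#' Write a coverage track as bedGraph
#'
#' @param track Coverage track tibble.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$pos + 1L,
                                                track$pos + 1L),
                               score = track$weight)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read / write a VCF-like SNP table
#'
#' Plain tab table with `chrom`, `pos` (0-based), `ref`, `alt`, `frac`.
#'
#' @param path File path.
#' @param snps SNP tibble.
#' @export
read_snp_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    frac = readr::col_double()))
}

#' @rdname read_snp_table
#' @export
write_snp_table <- function(snps, path) {
  readr::write_tsv(snps, path)
  invisible(path)
}

#' Write simulation ground truth as TSV
#'
#' @param truth Truth list from [simulate_reads()].
#' @param dir Output directory (files `truth_reads.tsv`,
#'   `truth_genes.tsv`, `truth_sites.tsv`).
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(truth$reads, file.path(dir, "truth_reads.tsv"))
  readr::write_tsv(truth$genes, file.path(dir, "truth_genes.tsv"))
  if (!is.null(truth$sites) && nrow(truth$sites) > 0) {
    readr::write_tsv(truth$sites, file.path(dir, "truth_sites.tsv"))
  }
  invisible(dir)
}

#' Read / write a simulation config as YAML
#'
#' @param config A [sim_config()].
#' @param path YAML path.
#' @export
write_sim_config <- function(config, path) {
  plain <- unclass(config)
  for (f in c("polymorphisms", "editing_sites", "contaminants")) {
    if (!is.null(plain[[f]])) plain[[f]] <- as.list(plain[[f]])
  }
  # yaml drops names of atomic vectors; maps preserve them
  for (f in c("readthrough_rate", "footprint_length_dist",
              "peak_multipliers")) {
    plain[[f]] <- as.list(plain[[f]])
  }
  yaml::write_yaml(plain, path, precision = 15L)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("polymorphisms", "editing_sites", "contaminants")) {
    if (!is.null(raw[[f]])) raw[[f]] <- as_tibble(raw[[f]])
  }
  for (f in c("readthrough_rate", "footprint_length_dist",
              "peak_multipliers")) {
    raw[[f]] <- unlist(raw[[f]])
  }
  do.call(sim_config, raw[setdiff(names(raw), character(0))])
}
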