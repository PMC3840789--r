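# Fixtures built in code: tiny hand-written transcript models and small
# seeded simulations shared across test files.

# One-row alignment constructor.
read1 <- function(chrom, pos, len, strand = "+", mm = NA_character_,
                  qname = "r1") {
  tibble::tibble(qname = qname, chrom = chrom, strand = strand,
                 pos = as.integer(pos), len = as.integer(len), mm = mm)
}

# A two-gene toy: one plus-strand and one minus-strand single-exon gene on
# separate chromosomes, with deterministic sequences. The plus gene's
# 3'UTR hosts a 6-codon in-frame extension ending at a TAA.
toy_models <- function() {
  # gpA (+): 12 nt UTR5 | ATG + 8 sense codons + TAA | 3'UTR
  cds_a <- paste0("ATG", "GCTGCCGCAGCGGATGACTGTTGC", "TAA")
  ext_a <- paste0("GCTGAAGCAGCGGATGAC", "TAA")       # 6 codons + stop
  utr3_a <- paste0(ext_a, strrep("CT", 30))
  seq_a <- paste0("AATTCCGGATCC", cds_a, utr3_a)
  chrA <- paste0(strrep("ACGGT", 4), seq_a, strrep("TGCAA", 4))
  # gpB (-): same structure, reverse-complemented onto the chromosome
  cds_b <- paste0("ATG", "AAAGACGATTTCTTTGGAGGC", "TGA")
  seq_b <- paste0("CCAATTGG", cds_b, "ATTATTGCCGCATTATTT")
  chrB <- paste0(strrep("CATGC", 4),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(seq_b))),
                 strrep("GGTAC", 4))
  genome <- c(chrA = chrA, chrB = chrB)
  pad <- 20L
  ann <- tibble::tibble(
    gene_id = c("gA", "gB"),
    transcript_id = c("gA.t1", "gB.t1"),
    chrom = c("chrA", "chrB"),
    strand = c("+", "-"),
    start = c(pad, pad),
    end = c(pad + nchar(seq_a), pad + nchar(seq_b)),
    cds_start = c(pad + 12L, NA),
    cds_stop = c(pad + 12L + nchar(cds_a) - 3L, NA),
    biotype = "protein_coding"
  )
  # minus strand: cds_start is the genomic coordinate of the first CDS
  # base in mRNA sense (right end on the chromosome)
  b_len <- nchar(seq_b)
  ann$cds_start[2] <- pad + b_len - 1L - 8L          # 8 nt UTR5
  ann$cds_stop[2] <- pad + b_len - 1L - 8L - (nchar(cds_b) - 3L)
  list(genome = genome, annotation = ann)
}

# Coverage track assembled directly from (chrom, strand, pos, weight).
manual_track <- function(chrom, strand, pos, weight,
                         class = "footprint") {
  tr <- tibble::tibble(chrom = chrom, strand = strand,
                       pos = as.integer(pos), weight = weight)
  structure(tr, class = c("coverage_track", class(tr)),
            track_class = class, n_reads = sum(weight), n_rejected = 0L)
}

# Small cached readthrough simulation shared by several tests.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_genes = 4,
                        readthrough_rate = c(g001 = 0.05, g002 = 0),
                        total_footprints = 2e5,
                        total_mrna_fragments = 4e4)
      tr <- generate_transcriptome(cfg)
      sim <- simulate_reads(cfg, tr$genome, tr$annotation)
      cache <<- list(cfg = cfg, tr = tr, sim = sim,
                     track = coverage_track(sim$footprints, "footprint"))
    }
    cache
  }
})

# Independent brute-force 29-mer degeneracy oracle: literally search every
# centred k-mer against the genome (both strands) and flag multi-hits.
oracle_degenerate <- function(genome, k = 29L) {
  half <- (k - 1L) %/% 2L
  fwd <- toupper(unlist(genome))
  rev_ <- vapply(fwd, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1))
  count_hits <- function(kmer) {
    sum(vapply(c(fwd, rev_), function(s) {
      length(gregexpr(kmer, s, fixed = TRUE)[[1]]) *
        (regexpr(kmer, s, fixed = TRUE) > 0)
    }, numeric(1)))
  }
  out <- list()
  for (ch in names(genome)) {
    s <- toupper(genome[[ch]])
    len <- nchar(s)
    for (i in seq.int(half, len - half - 1L)) {
      kmer <- substr(s, i - half + 1L, i + half + 1L)
      if (count_hits(kmer) > 1L) {
        out[[length(out) + 1L]] <- tibble::tibble(chrom = ch, pos = i)
      }
    }
  }
  dplyr::bind_rows(out)
}

# Independent literal-counting Z-curve oracle: nested loops with modular
# (cyclic) indexing, no shared code with zcurve_features().
oracle_zcurve <- function(window) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(toupper(window), "")[[1]]
  L <- length(chars) - length(chars) %% 3L
  chars <- chars[seq_len(L)]
  out <- numeric(0)
  for (k in 1:3) {
    ctxs <- if (k == 1) "" else {
      do.call(paste0, rev(expand.grid(rep(list(bases), k - 1),
                                      stringsAsFactors = FALSE)))
    }
    for (p in 0:2) {
      for (ctx in ctxs) {
        counts <- c(A = 0, C = 0, G = 0, T = 0)
        i <- p + 1L
        while (i <= L) {
          idx <- ((i - 1L + 0:(k - 1L)) %% L) + 1L
          kmer <- paste(chars[idx], collapse = "")
          if (k == 1 || substr(kmer, 1, k - 1) == ctx) {
            b <- substr(kmer, k, k)
            counts[b] <- counts[b] + 1
          }
          i <- i + 3L
        }
        tot <- sum(counts)
        f <- if (tot > 0) counts / tot else counts
        out <- c(out,
                 (f[["A"]] + f[["G"]]) - (f[["C"]] + f[["T"]]),
                 (f[["A"]] + f[["C"]]) - (f[["G"]] + f[["T"]]),
                 (f[["A"]] + f[["T"]]) - (f[["G"]] + f[["C"]]))
      }
    }
  }
  out
}

# Random windows with coding-like codon bias (for classifier tests).
biased_coding_window <- function(n_codons = 27) {
  preferred <- c("GCT", "AAA", "GAT", "TTC", "GGA", "CAT", "ATT", "CTG",
                 "AAC", "CCA", "CAG", "CGT", "TCC", "ACA", "GTG", "TGG",
                 "TAC", "ATG", "GAA", "TGC")
  other <- c("GCA", "AAG", "GAC", "TTT", "GGC", "CAC", "ATC", "CTA",
             "AAT", "CCG", "CAA", "CGC", "TCG", "ACG", "GTT", "TAT")
  paste(sample(c(rep(preferred, 5), other), n_codons, replace = TRUE),
        collapse = "")
}

uniform_window <- function(n_nt = 81) {
  paste(sample(c("A", "C", "G", "T"), n_nt, replace = TRUE), collapse = "")
}
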