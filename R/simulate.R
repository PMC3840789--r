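# Synthetic ribosome-profiling data with known ground truth. The generator
# emulates the statistical structure the analysis assumes: CDS-biased
# footprint density with initiation/termination peaks, 25-35 nt footprint
# lengths, optional triplet phasing, per-gene stop codon readthrough at
# configurable rates, 3'-UTR contaminants, sequencing mismatches, genomic
# polymorphisms and A-to-I editing sites.

STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  all <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                           c("T", "C", "A", "G")), 1, paste, collapse = "")
  setdiff(all, STOP_CODONS)
}

# Fixed, moderately biased codon usage: one preferred codon per amino acid.
# The bias creates the phased nucleotide composition that distinguishes
# coding from non-coding sequence (Z-curve separability) without mimicking
# any particular organism.
codon_usage_weights <- function() {
  codons <- sense_codons()
  aa <- vapply(codons, function(cd) {
    as.character(Biostrings::GENETIC_CODE[[cd]])
  }, character(1))
  w <- rep(1, length(codons))
  names(w) <- codons
  for (a in unique(aa)) {
    members <- codons[aa == a]
    w[members[1]] <- 5
  }
  w
}

#' Simulation configuration
#'
#' Bundles every generative quantity of the synthetic ribosome-profiling
#' forward model. Defaults define the reference study conditions; peak
#' heights and 3'-UTR background are free parameters (no quantitative
#' values exist for them) and are documented as such.
#'
#' @param seed Integer seed; the whole simulation is deterministic given the
#'   config (including this seed).
#' @param n_genes Number of genes (one per toy chromosome).
#' @param utr5_len,cds_len,utr3_len Length ranges in nt (`c(min, max)`);
#'   CDS lengths are rounded to whole codons. `utr3_len` is the distal
#'   budget downstream of any simulated extension.
#' @param readthrough_rate Named vector, gene id to readthrough fraction in
#'   [0, 1]. Genes named here (even at rate 0) get a 3'UTR hosting an
#'   in-frame next stop at least 5 codons downstream.
#' @param extension_codons Range of extension lengths in codons for
#'   readthrough genes.
#' @param double_readthrough_genes Genes whose extension is followed by a
#'   second in-frame extension read through at the same rate.
#' @param peak_multipliers Named vector `c(initiation=, termination=)`;
#'   extra occupancy (relative to mean CDS codon occupancy) at the
#'   initiation window (the codons around the start) and at the
#'   termination pause codon (stop codon in the A site, so the P-site
#'   peak sits one codon 5' of the stop). Must be >= 1.
#' @param include_termination_peaks Model flash-frozen samples (TRUE;
#'   termination blocked, stop codon peaks present) vs samples whose
#'   terminating ribosomes released during harvesting (FALSE, no stop
#'   peaks).
#' @param footprint_length_dist Probability vector over read lengths
#'   25-35 nt.
#' @param phasing_mode `"phased"` (RNase-I-like: P-sites codon-aligned with
#'   90/5/5 frame weights, fixed 5'+12 offset) or `"blurred"` (MNase-like
#'   positional uncertainty).
#' @param per_base_error Per-base sequencing mismatch probability.
#' @param polymorphisms,editing_sites Tibbles with `chrom`, `pos` (0-based),
#'   `alt`, `frac` (allele fraction); editing sites are A-to-G by
#'   convention.
#' @param contaminants Tibble with `gene_id`, `type`
#'   (`"frameshift"` or `"structure"`), `weight` (occupancy per codon
#'   relative to CDS codons).
#' @param uorf_genes Genes given a translated uORF in the 5'UTR (off by
#'   default; 5'UTR translation is a diagnostic, not a target).
#' @param background_utr3 Uniform 3'UTR occupancy per codon relative to
#'   CDS (default 0).
#' @param total_footprints,total_mrna_fragments Library sizes.
#' @param mrna_fragment_length Range of mRNA fragment lengths in nt.
#' @param abundance_sd Log-normal sd of per-gene transcript abundance.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 6L,
                       utr5_len = c(60L, 120L),
                       cds_len = c(300L, 600L),
                       utr3_len = c(250L, 450L),
                       readthrough_rate = numeric(0),
                       extension_codons = c(10L, 40L),
                       double_readthrough_genes = character(0),
                       peak_multipliers = c(initiation = 8, termination = 6),
                       include_termination_peaks = TRUE,
                       footprint_length_dist = NULL,
                       phasing_mode = c("blurred", "phased"),
                       per_base_error = 0.001,
                       polymorphisms = NULL,
                       editing_sites = NULL,
                       contaminants = NULL,
                       uorf_genes = character(0),
                       background_utr3 = 0,
                       total_footprints = 1e5,
                       total_mrna_fragments = 1e5,
                       mrna_fragment_length = c(40L, 70L),
                       abundance_sd = 0.5) {
  if (is.null(footprint_length_dist)) {
    footprint_length_dist <- setNames(
      c(2, 4, 8, 14, 20, 20, 14, 8, 5, 3, 2), as.character(25:35))
    footprint_length_dist <- footprint_length_dist / sum(footprint_length_dist)
  }
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    utr5_len = utr5_len, cds_len = cds_len, utr3_len = utr3_len,
    readthrough_rate = readthrough_rate,
    extension_codons = extension_codons,
    double_readthrough_genes = double_readthrough_genes,
    peak_multipliers = peak_multipliers,
    include_termination_peaks = include_termination_peaks,
    footprint_length_dist = footprint_length_dist,
    phasing_mode = match.arg(phasing_mode),
    per_base_error = per_base_error,
    polymorphisms = polymorphisms, editing_sites = editing_sites,
    contaminants = contaminants, uorf_genes = uorf_genes,
    background_utr3 = background_utr3,
    total_footprints = as.integer(total_footprints),
    total_mrna_fragments = as.integer(total_mrna_fragments),
    mrna_fragment_length = mrna_fragment_length,
    abundance_sd = abundance_sd
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param config A `sim_config`.
#' @return The config, invisibly, or an error.
#' @export
validate_sim_config <- function(config) {
  with(config, {
    if (abs(sum(footprint_length_dist) - 1) > 1e-9) {
      stop("footprint_length_dist must sum to 1 (within 1e-9)")
    }
    if (any(readthrough_rate < 0 | readthrough_rate > 1)) {
      stop("readthrough rates must lie in [0, 1]")
    }
    for (r in list(utr5_len, cds_len, utr3_len, extension_codons,
                   mrna_fragment_length)) {
      if (length(r) != 2 || any(r <= 0) || r[2] < r[1]) {
        stop("length ranges must be positive c(min, max)")
      }
    }
    if (any(peak_multipliers < 1)) stop("peak multipliers must be >= 1")
    if (per_base_error < 0 || per_base_error > 1) {
      stop("per_base_error must lie in [0, 1]")
    }
    needs_ext <- length(readthrough_rate) > 0 ||
      length(double_readthrough_genes) > 0
    if (needs_ext && utr3_len[1] < 130) {
      stop("utr3_len too short to host the distal window past an extension")
    }
    if (needs_ext && extension_codons[1] < 5) {
      stop("extensions must be at least 5 codons")
    }
  })
  invisible(config)
}

random_nt <- function(n, prob = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(prob), n, replace = TRUE, prob = prob), collapse = "")
}

random_sense_codons <- function(n, usage = codon_usage_weights(),
                                no_met_first3 = FALSE) {
  cods <- sample(names(usage), n, replace = TRUE, prob = usage)
  if (no_met_first3 && n >= 1) {
    k <- min(3, n)
    while (any(cods[1:k] == "ATG")) {
      cods[1:k][cods[1:k] == "ATG"] <-
        sample(setdiff(names(usage), "ATG"), sum(cods[1:k] == "ATG"),
               replace = TRUE)
    }
  }
  cods
}

# First in-frame stop at or after tx offset `from` (step 3); offset of its
# first base, or NA.
next_inframe_stop <- function(seq, from) {
  len <- nchar(seq)
  i <- from
  while (i + 3L <= len) {
    if (str_sub(seq, i + 1L, i + 3L) %in% STOP_CODONS) return(i)
    i <- i + 3L
  }
  NA_integer_
}

#' Generate a toy genome and annotation
#'
#' Builds one gene per chromosome (plus strand, single exon) with
#' 5'UTR/CDS/3'UTR structure. The CDS begins with ATG and ends in a stop
#' codon. Genes named in `readthrough_rate` (and double-readthrough genes)
#' get a 3'UTR that begins with a stop-free in-frame extension of the
#' configured length, so the next in-frame stop lies at least 5 codons
#' downstream; the extension's first three codons never contain ATG. The
#' result is byte-identical for identical config (including seed).
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector), `annotation`
#'   (exon-level tibble), and `genes` (per-gene ground truth: true
#'   readthrough rate, extension geometry in transcript coordinates).
#' @export
generate_transcriptome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  usage <- codon_usage_weights()
  pad <- 60L
  gene_ids <- sprintf("g%03d", seq_len(config$n_genes))
  rate_of <- function(g) {
    r <- config$readthrough_rate
    if (g %in% names(r)) unname(r[[g]]) else NA_real_
  }
  genome <- character(0)
  ann <- list()
  genes <- list()
  for (i in seq_len(config$n_genes)) {
    g <- gene_ids[i]
    u5 <- sample(seq.int(config$utr5_len[1], config$utr5_len[2]), 1)
    n_cod <- max(10L, round(sample(
      seq.int(config$cds_len[1], config$cds_len[2]), 1) / 3))
    utr5 <- random_nt(u5)
    cds <- paste0("ATG",
                  paste(random_sense_codons(n_cod - 2L, usage), collapse = ""),
                  sample(STOP_CODONS, 1))
    rate <- rate_of(g)
    structured <- !is.na(rate) || g %in% config$double_readthrough_genes
    ext_codons <- NA_integer_; ext2_codons <- NA_integer_
    if (structured) {
      ext_codons <- sample(seq.int(config$extension_codons[1],
                                   config$extension_codons[2]), 1)
      ext <- paste(random_sense_codons(ext_codons, usage,
                                       no_met_first3 = TRUE), collapse = "")
      tail3 <- random_nt(sample(seq.int(config$utr3_len[1],
                                        config$utr3_len[2]), 1))
      if (g %in% config$double_readthrough_genes) {
        ext2_codons <- sample(seq.int(config$extension_codons[1],
                                      config$extension_codons[2]), 1)
        ext2 <- paste(random_sense_codons(ext2_codons, usage,
                                          no_met_first3 = TRUE),
                      collapse = "")
        utr3 <- paste0(ext, sample(STOP_CODONS, 1), ext2,
                       sample(STOP_CODONS, 1), tail3)
      } else {
        utr3 <- paste0(ext, sample(STOP_CODONS, 1), tail3)
      }
    } else {
      utr3 <- random_nt(sample(seq.int(config$utr3_len[1],
                                       config$utr3_len[2]), 1))
    }
    tx <- paste0(utr5, cds, utr3)
    chrom_seq <- paste0(random_nt(pad), tx, random_nt(pad))
    chrom <- paste0("chr_", g)
    genome[chrom] <- chrom_seq
    ann[[g]] <- tibble(
      gene_id = g, transcript_id = paste0(g, ".t1"), chrom = chrom,
      strand = "+", start = pad, end = pad + nchar(tx),
      cds_start = pad + u5, cds_stop = pad + u5 + nchar(cds) - 3L,
      biotype = "protein_coding"
    )
    genes[[g]] <- tibble(
      gene_id = g, chrom = chrom, tx_len = nchar(tx),
      utr5_len = u5, cds_codons = n_cod,
      true_rate = if (is.na(rate)) 0 else rate,
      ext_codons = ext_codons, ext2_codons = ext2_codons,
      cds_start_tx = u5, stop_tx = u5 + nchar(cds) - 3L
    )
  }
  genes <- bind_rows(genes) |>
    mutate(
      ext_stop_tx = if_else(is.na(.data$ext_codons), NA_integer_,
                            .data$stop_tx + 3L + 3L * .data$ext_codons),
      ext2_stop_tx = if_else(is.na(.data$ext2_codons), NA_integer_,
                             .data$ext_stop_tx + 3L + 3L * .data$ext2_codons)
    )
  list(genome = genome, annotation = bind_rows(ann), genes = genes)
}

# Occupancy slots: one row per (gene, codon) with relative ribosome
# occupancy, provenance label and frame shift. P-site positions are drawn
# from these slots.
build_occupancy_slots <- function(config, genes) {
  m_init <- config$peak_multipliers[["initiation"]]
  m_term <- config$peak_multipliers[["termination"]]
  term_on <- config$include_termination_peaks
  out <- map(seq_len(nrow(genes)), function(i) {
    gi <- genes[i, ]
    s <- gi$cds_start_tx; t <- gi$stop_tx
    slot <- function(off, w, prov, shift = 0L, structure = FALSE) {
      tibble(gene_id = gi$gene_id, tx_off = off, w = w, provenance = prov,
             shift = shift, structure = structure)
    }
    rows <- list(
      # gi$cds_codons counts sense codons (stop codon excluded)
      slot(s + 3L * seq.int(0L, gi$cds_codons - 1L), 1, "CDS"),
      slot(c(s - 3L, s, s + 3L), m_init, "CDS")
    )
    # termination pause: the stop codon sits in the A site of the paused
    # ribosome, so the P-site peak occupies the codon 5' of the stop
    if (term_on) rows <- c(rows, list(slot(t - 3L, m_term, "CDS")))
    r <- gi$true_rate
    if (!is.na(gi$ext_codons) && r > 0) {
      u <- gi$ext_stop_tx
      rows <- c(rows, list(
        slot(t + 3L + 3L * seq.int(0L, gi$ext_codons - 1L), r, "extension")))
      if (term_on) {
        rows <- c(rows, list(slot(u - 3L, m_term * r,
                                  "extension")))
      }
      if (!is.na(gi$ext2_codons) && r > 0) {
        v <- gi$ext2_stop_tx
        rows <- c(rows, list(
          slot(u + 3L + 3L * seq.int(0L, gi$ext2_codons - 1L), r^2,
               "extension")))
        if (term_on) {
          rows <- c(rows, list(slot(v - 3L, m_term * r^2,
                                    "extension")))
        }
      }
    }
    if (config$background_utr3 > 0) {
      utr3_cod <- seq.int(t + 3L, gi$tx_len - 40L, by = 3L)
      rows <- c(rows, list(slot(utr3_cod, config$background_utr3,
                                "contaminant")))
    }
    if (gi$gene_id %in% config$uorf_genes && s >= 45L) {
      rows <- c(rows, list(slot(s - 36L + 3L * (0:5), 1, "uORF")))
    }
    if (!is.null(config$contaminants)) {
      cont <- filter(config$contaminants, .data$gene_id == gi$gene_id)
      for (j in seq_len(nrow(cont))) {
        if (cont$type[j] == "frameshift") {
          cods <- seq.int(t + 3L, gi$tx_len - 40L, by = 3L)
          rows <- c(rows, list(slot(cods, cont$weight[j], "contaminant",
                                    shift = 1L)))
        } else {
          rows <- c(rows, list(slot(t + 90L, cont$weight[j] * 20,
                                    "contaminant", structure = TRUE)))
        }
      }
    }
    bind_rows(rows)
  })
  bind_rows(out)
}

#' Simulate footprint and mRNA-fragment alignments
#'
#' Forward model: each footprint picks a gene (multinomial in transcript
#' abundance times total occupancy), then a codon slot in proportion to
#' occupancy (CDS codons at weight 1, extension codons at the gene's
#' readthrough rate, peak windows at the configured multipliers), then a
#' P-site nucleotide within the codon (90/5/5 frame weights when phased,
#' uniform when blurred), a read length from `footprint_length_dist`, and a
#' read placement consistent with the P-site trimming rule (exact 5'+12
#' offset when phased, uniform jitter of the pruned window when blurred).
#' Sequencing errors, polymorphisms and editing sites are injected as
#' per-base mismatches. Exactly the requested numbers of records are
#' emitted, and every footprint carries one provenance label.
#'
#' @param config A [sim_config()].
#' @param genome,annotation Output of [generate_transcriptome()] (the
#'   per-gene extension geometry is re-derived from the sequence).
#' @return List with `footprints` and `mrna` alignment tibbles and `truth`
#'   (list: `reads` qname-to-provenance, `genes` per-gene true rates,
#'   `sites` injected variant positions).
#' @export
simulate_reads <- function(config, genome, annotation) {
  validate_sim_config(config)
  if (config$total_footprints <= 0 || config$total_mrna_fragments <= 0) {
    stop("requested read counts must be positive")
  }
  set.seed((config$seed * 48271L) %% 2147483629L + 1L)
  txs <- split_transcripts(annotation)
  genes <- bind_rows(map(txs, function(tx) {
    b <- tx_cds_bounds(tx)
    seq_ <- tx_sequence(genome, tx)
    gi <- tibble(
      gene_id = tx$gene_id[1], chrom = tx$chrom[1],
      tx_start = min(tx$start), tx_len = sum(tx$end - tx$start),
      cds_start_tx = b[["cds"]], stop_tx = b[["stop"]],
      cds_codons = (b[["stop"]] - b[["cds"]]) %/% 3L + 1L
    )
    r <- config$readthrough_rate
    gi$true_rate <- if (gi$gene_id %in% names(r)) unname(r[[gi$gene_id]]) else 0
    u <- next_inframe_stop(seq_, gi$stop_tx + 3L)
    gi$ext_codons <- if (is.na(u)) NA_integer_ else (u - gi$stop_tx - 3L) %/% 3L
    gi$ext_stop_tx <- u
    v <- if (!is.na(u)) next_inframe_stop(seq_, u + 3L) else NA_integer_
    gi$ext2_codons <- if (is.na(v)) NA_integer_ else (v - u - 3L) %/% 3L
    gi$ext2_stop_tx <- v
    gi
  }))
  genes$cds_codons <- genes$cds_codons - 1L  # sense codons, stop excluded
  if (!(length(config$double_readthrough_genes) == 0)) {
    # second tier only for declared double-readthrough genes
    off <- !(genes$gene_id %in% config$double_readthrough_genes)
    genes$ext2_codons[off] <- NA_integer_
    genes$ext2_stop_tx[off] <- NA_integer_
  } else {
    genes$ext2_codons <- NA_integer_
    genes$ext2_stop_tx <- NA_integer_
  }
  genes$abundance <- rlnorm(nrow(genes), 0, config$abundance_sd)

  slots <- build_occupancy_slots(config, genes)
  slots <- left_join(slots,
                     select(genes, "gene_id", "chrom", "tx_start",
                            "abundance"),
                     by = "gene_id")
  prob <- slots$w * slots$abundance
  n_fp <- config$total_footprints

  draw <- sample.int(nrow(slots), n_fp, replace = TRUE, prob = prob)
  sl <- slots[draw, ]
  phase <- sample.int(3L, n_fp, replace = TRUE,
                      prob = c(0.9, 0.05, 0.05)) - 1L
  phase <- (phase + sl$shift) %% 3L
  phase[sl$structure] <- 0L
  p <- sl$tx_start + sl$tx_off + phase   # genomic P-site nucleotide
  len <- sample(as.integer(names(config$footprint_length_dist)), n_fp,
                replace = TRUE, prob = config$footprint_length_dist)
  start <- if (config$phasing_mode == "phased") {
    # fixed 5'+12 offset: the 5'-most pruned position is the P-site
    p - PSITE_TRIM
  } else {
    # MNase-like positional uncertainty: centre the pruned window on the
    # P-site and add +/- 2 nt jitter
    p - PSITE_TRIM - (len - 2L * PSITE_TRIM - 1L) %/% 2L -
      sample(seq.int(-2L, 2L), n_fp, replace = TRUE)
  }
  fp <- tibble(
    qname = sprintf("fp%07d", seq_len(n_fp)),
    chrom = sl$chrom, strand = "+", pos = as.integer(start), len = len,
    mm = NA_character_
  )
  fp_prov <- tibble(qname = fp$qname, gene_id = sl$gene_id,
                    provenance = sl$provenance)

  n_mr <- config$total_mrna_fragments
  gdraw <- sample.int(nrow(genes), n_mr, replace = TRUE,
                      prob = genes$abundance * genes$tx_len)
  mlen <- sample(seq.int(config$mrna_fragment_length[1],
                         config$mrna_fragment_length[2]),
                 n_mr, replace = TRUE)
  gstart <- genes$tx_start[gdraw] +
    floor(runif(n_mr) * pmax(1L, genes$tx_len[gdraw] - mlen + 1L))
  mr <- tibble(
    qname = sprintf("mr%07d", seq_len(n_mr)),
    chrom = genes$chrom[gdraw], strand = "+",
    pos = as.integer(gstart), len = mlen, mm = NA_character_
  )

  fp <- inject_mismatches(fp, genome, config)
  mr <- inject_mismatches(mr, genome, config)

  truth <- list(
    reads = bind_rows(fp_prov,
                      tibble(qname = mr$qname, gene_id = genes$gene_id[gdraw],
                             provenance = "mrna")),
    genes = select(genes, "gene_id", "chrom", "true_rate", "ext_codons",
                   "ext_stop_tx", "ext2_codons", "cds_codons"),
    sites = bind_rows(
      if (!is.null(config$polymorphisms)) {
        mutate(config$polymorphisms, kind = "polymorphism")
      },
      if (!is.null(config$editing_sites)) {
        mutate(config$editing_sites, kind = "editing")
      }
    )
  )
  list(footprints = fp, mrna = mr, truth = truth)
}

# Append "offset:REF>ALT" mismatch records for sequencing errors and for
# configured polymorphism/editing sites.
inject_mismatches <- function(reads, genome, config) {
  n <- nrow(reads)
  mm <- rep(NA_character_, n)
  base_at <- function(chrom, pos) {
    str_sub(genome[chrom], pos + 1L, pos + 1L)
  }
  add_mm <- function(i, off, ref, alt) {
    rec <- paste0(off, ":", ref, ">", alt)
    mm[i] <<- if_else(is.na(mm[i]), rec, paste(mm[i], rec, sep = ","))
  }
  if (config$per_base_error > 0) {
    k <- rbinom(n, reads$len, config$per_base_error)
    for (i in which(k > 0)) {
      offs <- sample.int(reads$len[i], k[i]) - 1L
      for (off in offs) {
        ref <- base_at(reads$chrom[i], reads$pos[i] + off)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        add_mm(i, off, ref, alt)
      }
    }
  }
  sites <- bind_rows(config$polymorphisms, config$editing_sites)
  if (!is.null(sites) && nrow(sites) > 0) {
    for (j in seq_len(nrow(sites))) {
      cover <- which(reads$chrom == sites$chrom[j] &
                       reads$pos <= sites$pos[j] &
                       reads$pos + reads$len > sites$pos[j])
      if (length(cover) == 0) next
      carrier <- cover[runif(length(cover)) < sites$frac[j]]
      ref <- base_at(sites$chrom[j], sites$pos[j])
      for (i in carrier) add_mm(i, sites$pos[j] - reads$pos[i], ref,
                                sites$alt[j])
    }
  }
  # canonical order: mismatch records sorted by alignment offset
  multi <- which(!is.na(mm) & grepl(",", mm))
  for (i in multi) {
    parts <- strsplit(mm[i], ",", fixed = TRUE)[[1]]
    off <- as.integer(sub(":.*", "", parts))
    mm[i] <- paste(parts[order(off)], collapse = ",")
  }
  reads$mm <- mm
  reads
}
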