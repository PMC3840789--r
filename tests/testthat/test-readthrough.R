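# Candidate enumeration, filters, scoring, rate recovery, differential
# readthrough.

# A configurable single-gene toy: 3'UTR sequence supplied directly.
gene_with_utr3 <- function(utr3, cds_codons = 40) {
  utr5 <- strrep("CT", 15)
  set.seed(99)
  body <- paste(sample(c("GCT", "GAA", "CCA", "AAG", "GAT", "TGC"),
                       cds_codons - 2, TRUE), collapse = "")
  cds <- paste0("ATG", body, "TAA")
  seq_ <- paste0(utr5, cds, utr3)
  pad <- 25L
  genome <- c(chr1 = paste0(strrep("GATCA", 5), seq_, strrep("CTTAG", 12)))
  ann <- tibble::tibble(
    gene_id = "g1", transcript_id = "g1.t1", chrom = "chr1", strand = "+",
    start = pad, end = pad + nchar(seq_),
    cds_start = pad + 30L, cds_stop = pad + 30L + nchar(cds) - 3L,
    biotype = "protein_coding"
  )
  list(genome = genome, annotation = ann,
       stop_pos = ann$cds_stop, ext_start = ann$cds_stop + 3L)
}

test_that("candidate enumeration frame-walks to the next in-frame stop", {
  # extension of 8 sense codons, then TAA, then filler
  g <- gene_with_utr3(paste0(strrep("GCA", 8), "TAA", strrep("CT", 70)))
  cand <- enumerate_candidates(g$annotation, g$genome)
  c1 <- cand[cand$tier == 1, ]
  expect_equal(nrow(c1), 1)
  expect_equal(c1$ext_codons, 8L)
  expect_equal(c1$stop_pos, g$stop_pos)
  expect_equal(c1$next_stop_pos, g$ext_start + 24L)
  expect_equal(c1$ext_pos[[1]], seq.int(g$ext_start, g$ext_start + 23L))
})

test_that("extensions shorter than five codons are excluded", {
  g <- gene_with_utr3(paste0(strrep("GCA", 4), "TAA", strrep("CT", 70)))
  cand <- enumerate_candidates(g$annotation, g$genome)
  expect_equal(nrow(cand), 0)
})

test_that("methionine in the first three codons excludes unless whitelisted", {
  utr3 <- paste0("GCAATGGCA", strrep("GAA", 6), "TAA", strrep("CT", 70))
  g <- gene_with_utr3(utr3)
  expect_equal(nrow(enumerate_candidates(g$annotation, g$genome)), 0)
  wl <- enumerate_candidates(g$annotation, g$genome,
                             met_whitelist = "g1")
  expect_equal(nrow(wl[wl$tier == 1, ]), 1)
})

test_that("overlap with disqualifying annotation drops the candidate", {
  g <- gene_with_utr3(paste0(strrep("GCA", 8), "TAA", strrep("CT", 70)))
  excl <- tibble::tibble(chrom = "chr1", pos = g$ext_start + 5L)
  expect_equal(nrow(enumerate_candidates(g$annotation, g$genome,
                                         exclusions = excl)), 0)
})

test_that("the distal window extends genomically to 114 nt when the UTR is short", {
  g <- gene_with_utr3(paste0(strrep("GCA", 8), "TAA", strrep("CT", 10)))
  cand <- enumerate_candidates(g$annotation, g$genome)
  expect_gte(length(cand$distal_pos[[1]]), 114)
})

test_that("the minimum-rho isoform is reported", {
  g <- gene_with_utr3(paste0(strrep("GCA", 8), "TAA", strrep("CT", 70)))
  ann <- g$annotation
  # a second isoform with a longer 5'UTR (same CDS, same extension)
  iso2 <- ann
  iso2$transcript_id <- "g1.t2"
  iso2$start <- ann$start + 6L
  ann2 <- dplyr::bind_rows(ann, iso2)
  cand <- enumerate_candidates(ann2, g$genome)
  expect_equal(length(cand$transcript_ids[[1]]), 2)
  cds_a <- ribostop:::masked_cds_positions(ann[1, ])
  # uneven coverage across the CDS makes the isoforms score differently
  trk <- manual_track("chr1", "+", c(cds_a$pos, g$ext_start + 12L),
                      c(rep(3, nrow(cds_a)), 1))
  rec <- readthrough_rate(cand[cand$tier == 1, ], ann2, trk,
                          library_size = 1e6, min_cds_reads = 1)
  per_iso <- vapply(c("g1.t1", "g1.t2"), function(txid) {
    cds <- ribostop:::masked_cds_positions(ann2[ann2$transcript_id ==
                                                  txid, ])
    ribostop:::region_count(trk, cds) / nrow(cds)
  }, numeric(1))
  expect_equal(rec$transcript_id, names(which.max(per_iso)))
})

test_that("filters fire at the documented thresholds", {
  g <- gene_with_utr3(paste0(strrep("GCA", 40), "TAA", strrep("CT", 80)))
  cand <- enumerate_candidates(g$annotation, g$genome)[1, ]
  cds <- ribostop:::masked_cds_positions(g$annotation)
  ext <- cand$ext_pos[[1]]
  lib <- 1e6
  run <- function(ext_pos, ext_w, cds_w = 50) {
    trk <- manual_track("chr1", "+", c(cds$pos, ext_pos),
                        c(rep(cds_w, nrow(cds)), ext_w))
    rec <- readthrough_rate(cand, g$annotation, trk, lib,
                            min_cds_reads = 1)
    apply_filters(rec, trk, lib)
  }
  # (a) extension density below 0.2 RPKM fails;
  #     ext has 96 masked nt -> 0.2 RPKM at lib 1e6 is ~0.0192 reads
  low <- run(ext[15], 0.001)
  expect_false(low$filter_a)
  # (b) rho below 0.001 fails even with density above the floor
  mid <- run(ext, rep(0.012, length(ext)), cds_w = 400)
  expect_true(mid$filter_a)
  expect_false(mid$filter_b)
  # (c)-(e): coverage fraction and first/last quartile
  early <- run(ext[1:6], rep(1, 6))
  expect_false(early$filter_e)
  expect_true(early$filter_d)
  # (f): a 70% drop into the distal window is not enough
  dense <- run(c(ext, cand$distal_pos[[1]][1:114]),
               c(rep(1, length(ext)), rep(0.3, 114)))
  expect_false(dense$filter_f)
  expect_lt(abs(dense$drop_fraction - 0.7), 0.05)
  full <- run(ext, rep(1, length(ext)))
  expect_true(all(full$filter_a, full$filter_b, full$filter_c,
                  full$filter_d, full$filter_e, full$filter_f,
                  full$even_spaced))
})

test_that("scoring: dense positive, early-only negative, sparse peak relaxation", {
  g <- gene_with_utr3(paste0(strrep("GCA", 40), "TAA", strrep("CT", 80)))
  cand <- enumerate_candidates(g$annotation, g$genome)[1, ]
  cds <- ribostop:::masked_cds_positions(g$annotation)
  ext <- cand$ext_pos[[1]]
  lib <- 1e6
  score_of <- function(ext_pos, ext_w) {
    trk <- manual_track("chr1", "+", c(cds$pos, ext_pos),
                        c(rep(2, nrow(cds)), ext_w))
    rec <- readthrough_rate(cand, g$annotation, trk, lib,
                            min_cds_reads = 1) |>
      apply_filters(trk, lib) |>
      score_candidates()
    rec$score
  }
  expect_equal(score_of(ext, rep(1, length(ext))), "readthrough")
  expect_equal(score_of(ext[1:10], rep(2, 10)), "negative")
  stop_cod <- cand$ext_stop_codon_pos[[1]]
  expect_equal(score_of(c(ext[30], stop_cod), c(0.4, rep(1, 3))),
               "readthrough")
  # even coverage that narrowly misses the last-quartile criterion only
  expect_equal(score_of(ext[1:85], rep(1, 85)), "ambiguous")
})

test_that("simulated rates are recovered within 20% at deep coverage", {
  s <- small_sim()   # g001 at rate 0.05, 2e5 footprints over 4 genes
  cand <- enumerate_candidates(s$tr$annotation, s$tr$genome)
  rec <- detect_readthrough(cand, s$tr$annotation, s$track,
                            nrow(s$sim$footprints))
  r1 <- rec[rec$gene_id == "g001" & rec$tier == 1, ]
  expect_equal(r1$score, "readthrough")
  expect_lt(abs(r1$rho / 0.05 - 1), 0.20)
  r0 <- rec[rec$gene_id == "g002" & rec$tier == 1, ]
  expect_false(r0$score == "readthrough")
})

test_that("double readthrough is detected and limited to positive parents", {
  cfg <- sim_config(seed = 77, n_genes = 2,
                    readthrough_rate = c(g001 = 0.2, g002 = 0),
                    double_readthrough_genes = "g001",
                    total_footprints = 4e5, total_mrna_fragments = 1e4)
  tr <- generate_transcriptome(cfg)
  sim <- simulate_reads(cfg, tr$genome, tr$annotation)
  trk <- coverage_track(sim$footprints, "footprint")
  cand <- enumerate_candidates(tr$annotation, tr$genome)
  rec <- detect_readthrough(cand, tr$annotation, trk, nrow(sim$footprints))
  t2 <- rec[rec$tier == 2 & rec$gene_id == "g001", ]
  expect_equal(nrow(t2), 1)
  expect_equal(t2$score, "readthrough")
  expect_lt(abs(t2$rho / 0.04 - 1), 0.5)   # true second-tier rate 0.2^2
  # no tier-2 rows survive for genes without a positive tier-1 call
  expect_false(any(rec$tier == 2 & rec$gene_id == "g002"))
})

test_that("differential readthrough reproduces fold-change arithmetic and Fisher calls", {
  base <- tibble::tibble(
    candidate_id = c("c:100-160(+)", "c:300-360(+)", "c:500-560(+)"),
    tier = 1L, gene_id = c("gX", "gY", "gZ"), same_cds = TRUE,
    score = "readthrough"
  )
  r1 <- dplyr::mutate(base, cds_count = c(2e4, 2e4, 1e4),
                      ext_count = c(14300, 176, 200),
                      rho = c(7.15e-1, 8.82e-3, 2e-2))
  r2 <- dplyr::mutate(base, cds_count = c(2e4, 2e4, 1e4),
                      ext_count = c(49, 242, 200),
                      rho = c(2.46e-3, 1.21e-2, 2e-2))
  res <- differential_readthrough(r1, r2)
  res <- res[match(base$candidate_id, res$candidate_id), ]
  expect_equal(round(res$log10_fold, 2), c(-2.46, 0.14, 0))
  expect_equal(res$direction[1:2], c("down", "up"))
  # identical tables are never significant
  expect_equal(res$p[3], 1)
  expect_false(res$significant[3])
  expect_true(res$significant[1])
})

test_that("differential eligibility rules exclude with reasons", {
  base <- tibble::tibble(
    candidate_id = c("a", "b", "c"), tier = 1L,
    gene_id = c("g1", "g2", "g3"),
    same_cds = c(FALSE, TRUE, TRUE),
    score = c("readthrough", "negative", "readthrough"),
    cds_count = c(500, 500, 50), ext_count = c(5, 5, 5),
    rho = 0.01
  )
  other <- dplyr::mutate(base, same_cds = base$same_cds,
                         score = c("readthrough", "negative",
                                   "readthrough"))
  res <- differential_readthrough(base, other)
  inel <- attr(res, "ineligible")
  expect_equal(nrow(res), 0)
  expect_setequal(inel$candidate_id, c("a", "b", "c"))
})
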