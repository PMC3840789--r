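# Metagene profiles, release scores, length distributions, phasing.

sig_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ld <- setNames(c(0.2, 0.6, 0.2), 27:29)
      cfg <- sim_config(seed = 7, n_genes = 10,
                        readthrough_rate = c(g001 = 0.1, g002 = 0.1),
                        total_footprints = 2e5, total_mrna_fragments = 2e5,
                        phasing_mode = "phased",
                        footprint_length_dist = ld)
      tr <- generate_transcriptome(cfg)
      sim <- simulate_reads(cfg, tr$genome, tr$annotation)
      cache <<- list(cfg = cfg, tr = tr, sim = sim,
                     track = coverage_track(sim$footprints, "footprint"))
    }
    cache
  }
})

test_that("metagene normalisation maps uniform coverage to 1 and ignores per-ROI scale", {
  ann <- tibble::tibble(
    gene_id = c("g1", "g2"), transcript_id = c("g1.t", "g2.t"),
    chrom = c("c1", "c2"), strand = "+", start = 0L, end = 400L,
    cds_start = 90L, cds_stop = 297L, biotype = "protein_coding"
  )
  trk <- manual_track(rep(c("c1", "c2"), each = 400), "+",
                      rep(0:399, 2), c(rep(0.4, 400), rep(7, 400)))
  rois <- tibble::tibble(transcript_id = c("g1.t", "g2.t"))
  mp <- metagene_profile(rois, ann, trk, "stop")
  expect_true(all(abs(mp$median_density - 1) < 1e-9))
  expect_equal(mp$n_roi[1], 2)
  expect_error(metagene_profile(rois[1, ], ann, trk), "2 ROIs")
})

test_that("termination peaks appear in the metagene and vanish when disabled", {
  s <- sig_sim()
  rois <- select_metagene_rois(s$tr$annotation, s$track, "stop")
  expect_gte(nrow(rois), 5)
  mp <- metagene_profile(rois, s$tr$annotation, s$track, "stop")
  near <- max(mp$median_density[mp$offset %in% -6:2])
  flank <- median(mp$median_density[mp$offset < -20])
  expect_gt(near, 3 * flank)
  cfg_off <- s$cfg
  cfg_off$include_termination_peaks <- FALSE
  sim2 <- simulate_reads(cfg_off, s$tr$genome, s$tr$annotation)
  trk2 <- coverage_track(sim2$footprints, "footprint")
  mp2 <- metagene_profile(select_metagene_rois(s$tr$annotation, trk2,
                                               "stop"),
                          s$tr$annotation, trk2, "stop")
  near2 <- max(mp2$median_density[mp2$offset %in% -6:2])
  expect_lt(near2, 1.6)
})

test_that("release scores follow their definition", {
  # 50 upstream reads, 1 downstream
  trk <- manual_track("c", "+", c(90:104, 120), c(rep(50 / 15, 15), 1))
  cod <- tibble::tibble(chrom = "c", strand = "+", pos = 105L)
  rs <- release_score(cod, trk)
  expect_equal(rs$score, 0.02)
  trk2 <- manual_track("c", "+", c(95, 115), c(4, 4))
  expect_equal(release_score(cod, trk2)$score, 1)
  empty_up <- manual_track("c", "+", 115, 4)
  expect_true(is.na(release_score(cod, empty_up)$score))
})

test_that("true termination sites release ribosomes; internal codons do not", {
  s <- sig_sim()
  stops <- stop_codon_positions(s$tr$annotation, s$tr$genome) |>
    dplyr::filter(offset == 1) |>
    dplyr::select(chrom, strand, pos)
  rs <- release_score(stops, s$track)
  expect_lt(median(rs$score, na.rm = TRUE), 0.05)
  set.seed(6)
  internal <- dplyr::bind_rows(lapply(
    split(s$tr$annotation, s$tr$annotation$transcript_id), function(tx) {
      cods <- seq(tx$cds_start[1] + 30, tx$cds_stop[1] - 30, by = 3)
      tibble::tibble(chrom = tx$chrom[1], strand = "+",
                     pos = sample(cods, 5))
    }))
  ri <- release_score(internal, s$track)
  cmp <- rank_sum(ri$score[!is.na(ri$score)], rs$score[!is.na(rs$score)],
                  "greater")
  expect_lt(cmp$p, 0.01)
})

test_that("length distributions are compared by total variation distance", {
  mk <- function(lens, pos0 = 100L) {
    tibble::tibble(qname = paste0("r", seq_along(lens)), chrom = "c",
                   strand = "+", pos = pos0, len = lens,
                   mm = NA_character_)
  }
  region <- tibble::tibble(chrom = "c", strand = "+", pos = 100:160)
  a <- length_distribution(mk(rep(c(28L, 29L), 50)), region)
  b <- length_distribution(mk(rep(c(28L, 29L), 50)), region)
  expect_equal(tv_distance(a, b), 0)
  shifted <- length_distribution(mk(rep(c(33L, 34L), 50)), region)
  expect_gt(tv_distance(a, shifted), 0.2)
  point <- length_distribution(mk(rep(28L, 30)), region)
  expect_equal(point$fraction[point$len == 28], 1)
  expect_error(length_distribution(mk(integer(0)), region), "one read")
})

test_that("footprints in CDS and extensions share a length distribution in simulation", {
  s <- sig_sim()
  cand <- enumerate_candidates(s$tr$annotation, s$tr$genome)
  c1 <- cand[cand$tier == 1 & cand$gene_id == "g001", ]
  ext_pos <- tibble::tibble(chrom = c1$chrom, strand = "+",
                            pos = c1$ext_pos[[1]])
  tx <- s$tr$annotation[s$tr$annotation$gene_id == "g001", ]
  cds_pos <- tibble::tibble(chrom = tx$chrom, strand = "+",
                            pos = (tx$cds_start + 15):(tx$cds_stop - 16))
  d_cds <- length_distribution(s$sim$footprints, cds_pos)
  d_ext <- length_distribution(s$sim$footprints, ext_pos)
  expect_lt(tv_distance(d_cds, d_ext), 0.1)
})

test_that("phasing chi-square matches closed forms on constructed counts", {
  # frames (150, 75, 75) against a uniform 300-read expectation
  regions <- tibble::tibble(region = "CDS", chrom = "c", strand = "+",
                            pos = 0:299, frame = rep(0:2, 100))
  mk_fp <- function(frames) {
    pos <- unlist(lapply(seq_along(frames), function(i) {
      rep(((i - 1) * 3) %% 300 + frames[i], 1)
    }))
    tibble::tibble(qname = paste0("f", seq_along(pos)), chrom = "c",
                   strand = "+", pos = as.integer(pos - 12L), len = 28L,
                   mm = NA_character_)
  }
  fp <- mk_fp(c(rep(0, 150), rep(1, 75), rep(2, 75)))
  pt <- phasing_test(fp, fp, regions, expected = "uniform")
  expect_equal(pt$statistic, 37.5)
  expect_equal(pt$dof, 2L)
  even <- mk_fp(rep(0:2, 100))
  pt0 <- phasing_test(even, even, regions, expected = "uniform")
  expect_equal(pt0$statistic, 0)
})

test_that("phased extensions are translated in the CDS frame", {
  s <- sig_sim()
  cand <- enumerate_candidates(s$tr$annotation, s$tr$genome)
  regs <- region_frames(s$tr$annotation, cand)
  pt <- phasing_test(s$sim$footprints, s$sim$mrna, regs)
  cds <- pt[pt$region == "CDS", ]
  ext <- pt[pt$region == "extension", ]
  expect_gt(cds$frame0, 3 * (cds$frame1 + cds$frame2))
  expect_gt(ext$frame0, 3 * (ext$frame1 + ext$frame2))
  expect_lt(ext$p, 1e-6)
  # mRNA control is roughly uniform
  expect_lt(max(abs(cds[, c("mrna_frame0", "mrna_frame1",
                            "mrna_frame2")] /
                      sum(cds[, c("mrna_frame0", "mrna_frame1",
                                  "mrna_frame2")]) - 1 / 3)), 0.05)
})

test_that("frameshift contaminants phase out of frame and score negative", {
  ld <- setNames(c(0.2, 0.6, 0.2), 27:29)
  cfg <- sim_config(seed = 15, n_genes = 2,
                    readthrough_rate = c(g001 = 0),
                    contaminants = tibble::tibble(
                      gene_id = "g001", type = "frameshift", weight = 0.6),
                    total_footprints = 2e5, total_mrna_fragments = 1e5,
                    phasing_mode = "phased", footprint_length_dist = ld)
  tr <- generate_transcriptome(cfg)
  sim <- simulate_reads(cfg, tr$genome, tr$annotation)
  trk <- coverage_track(sim$footprints, "footprint")
  cand <- enumerate_candidates(tr$annotation, tr$genome)
  regs <- region_frames(tr$annotation, cand)
  pt <- phasing_test(sim$footprints, sim$mrna, regs)
  ext <- pt[pt$region == "extension", ]
  # dominant frame in the contaminated extension is +1, not the CDS frame
  expect_gt(ext$frame1, ext$frame0)
  rec <- detect_readthrough(cand, tr$annotation, trk,
                            nrow(sim$footprints))
  expect_false(any(rec$score == "readthrough" &
                     rec$gene_id == "g001" & rec$tier == 1 &
                     !is.na(rec$rho)))
})
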