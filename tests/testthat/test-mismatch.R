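# Mismatch tabulation over stop codons, elevated-mismatch testing,
# polymorphism/editing classification.

toy_stop <- function() {
  # one stop codon TAA at positions 100-102 on a plus-strand gene
  tibble::tibble(stop_id = "s1", offset = 1:3, chrom = "c", strand = "+",
                 pos = 100:102, ref = c("T", "A", "A"))
}

test_that("mismatch tabulation counts matches and substitution classes", {
  stops <- toy_stop()
  reads <- dplyr::bind_rows(
    lapply(1:9, function(i) read1("c", 90, 30, qname = paste0("m", i))),
    read1("c", 90, 30, mm = "11:A>G", qname = "x1")  # offset 11 = pos 101
  )
  tab <- tabulate_mismatches(reads, stops, "footprints_all")
  r2 <- tab[tab$offset == 2, ]
  expect_equal(r2$m, 9L)
  expect_equal(r2$x, 1L)
  expect_equal(r2$classes[[1]], c("A>G" = 1L))
  expect_equal(tab$x[tab$offset == 1], 0L)
})

test_that("the first aligned base contributes to neither tally", {
  stops <- toy_stop()
  reads <- dplyr::bind_rows(
    read1("c", 101, 30, mm = "0:A>G", qname = "first_mm"),
    read1("c", 101, 30, qname = "first_ok")
  )
  tab <- tabulate_mismatches(reads, stops, "footprints_all")
  r2 <- tab[tab$offset == 2, ]
  expect_equal(r2$m + r2$x, 0L)   # both excluded at their first base
  # the same reads do count at the third stop base
  r3 <- tab[tab$offset == 3, ]
  expect_equal(r3$m, 2L)
  # on the minus strand the first aligned base is the right end
  stops_m <- dplyr::mutate(toy_stop(), strand = "-", ref = c("T", "A", "A"))
  rev_read <- read1("c", 73, 30, strand = "-", qname = "rm")  # ends at 102
  tab_m <- tabulate_mismatches(rev_read, stops_m, "footprints_all")
  expect_equal(tab_m$m[tab_m$pos == 102], 0L)
  expect_equal(tab_m$m[tab_m$pos == 101], 1L)
})

test_that("the A-site-passed subset requires the P-site window past the position", {
  stops <- toy_stop()
  reads <- dplyr::bind_rows(
    read1("c", 95, 30, qname = "behind"),   # pruned window 107..112
    read1("c", 85, 30, qname = "covering")  # pruned window 97..102
  )
  all_t <- tabulate_mismatches(reads, stops, "footprints_all")
  ap <- tabulate_mismatches(reads, stops, "footprints_Apassed")
  expect_equal(all_t$m[all_t$offset == 1], 2L)
  expect_equal(ap$m[ap$offset == 1], 1L)     # only the passed read
  # subset property on simulated data
  s <- small_sim()
  st <- stop_codon_positions(s$tr$annotation, s$tr$genome)
  t_all <- tabulate_mismatches(s$sim$footprints, st, "footprints_all")
  t_ap <- tabulate_mismatches(s$sim$footprints, st, "footprints_Apassed")
  expect_true(all(t_ap$m + t_ap$x <= t_all$m + t_all$x))
})

test_that("elevated-mismatch testing is one-sided greater with BH control", {
  # 30 clean positions and one with 5/10 mismatches
  tab <- dplyr::bind_rows(
    tibble::tibble(stop_id = paste0("s", 1:30), offset = 1L, chrom = "c",
                   strand = "+", pos = 1:30, ref = "T", m = 100L, x = 0L,
                   classes = lapply(1:30, function(i) integer(0)),
                   dataset = "mrna"),
    tibble::tibble(stop_id = "hot", offset = 1L, chrom = "c",
                   strand = "+", pos = 500L, ref = "T", m = 5L, x = 5L,
                   classes = list(c("T>C" = 5L)), dataset = "mrna")
  )
  res <- elevated_mismatch_test(tab)
  hot <- res[res$stop_id == "hot", ]
  expect_true(hot$significant)
  expect_equal(hot$p,
               binomial_tail(5, 10, hot$global_rate, "greater"))
  expect_false(any(res$significant[res$x == 0]))
  expect_true(all(res$p[res$x == 0] == 1))
})

test_that("classification separates polymorphism kinds, editing and error", {
  stops <- dplyr::bind_rows(
    toy_stop(),                                        # TAA
    dplyr::mutate(toy_stop(), stop_id = "s2", pos = 200:202,
                  ref = c("T", "G", "A")),             # TGA
    dplyr::mutate(toy_stop(), stop_id = "s3", pos = 300:302),
    dplyr::mutate(toy_stop(), stop_id = "s4", pos = 400:402)
  )
  calls <- tibble::tibble(
    stop_id = c("s1", "s2", "s3", "s4"),
    offset = c(2L, 2L, 2L, 2L),
    chrom = "c", strand = "+", pos = c(101L, 201L, 301L, 401L),
    ref = c("A", "G", "A", "A"),
    m = c(0L, 0L, 80L, 80L),
    x = c(30L, 25L, 20L, 20L),
    classes = list(c("A>G" = 30L), c("G>C" = 25L), c("A>T" = 18L,
                                                     "A>C" = 2L),
                   c("A>G" = 19L, "A>C" = 1L)),
    dataset = "footprints_all",
    n = c(30L, 25L, 100L, 100L),
    global_rate = 0.001, tested = TRUE, p = 1e-10, q = 1e-9,
    significant = TRUE
  )
  cls <- classify_calls(calls, stops)
  expect_equal(cls$classification,
               c("stop_to_stop_polymorphism",      # TAA -> TGA
                 "stop_to_sense_polymorphism",     # TGA -> TCA (Ser)
                 "sequencing_error",               # A>T transversions
                 "editing_candidate"))             # low-frequency A>G
  expect_equal(cls$exclude_transcript,
               c(FALSE, TRUE, FALSE, FALSE))
})

test_that("the 90% editing null gives closed-form tail probabilities", {
  tab <- tibble::tibble(
    stop_id = c("e1", "e2"), offset = 2L, chrom = "c", strand = "+",
    pos = c(101L, 201L), ref = "A",
    m = c(50L, 1L), x = c(0L, 9L),
    classes = list(integer(0), c("A>G" = 9L)),
    dataset = "footprints_Apassed"
  )
  res <- editing_null_test(tab)
  e1 <- res[res$stop_id == "e1", ]
  expect_equal(e1$p, 0.1^50, tolerance = 1e-8)
  expect_true(e1$editing_rejected)
  e2 <- res[res$stop_id == "e2", ]
  expect_equal(e2$p, pbinom(9, 10, 0.9), tolerance = 1e-10)
  expect_false(e2$editing_rejected)
})

test_that("injected variants are recovered end to end", {
  cfg0 <- sim_config(seed = 11, n_genes = 6,
                     readthrough_rate = c(g001 = 0.1),
                     total_footprints = 1e5, total_mrna_fragments = 5e4)
  tr <- generate_transcriptome(cfg0)
  stops <- stop_codon_positions(tr$annotation, tr$genome)
  # homozygous stop->sense polymorphism at g002's stop (TGA -> CGA) and a
  # high-frequency editing site in g001's stop (TAA offset 2)
  cfg <- sim_config(seed = 11, n_genes = 6,
                    readthrough_rate = c(g001 = 0.1),
                    total_footprints = 1e5, total_mrna_fragments = 5e4,
                    polymorphisms = tibble::tibble(
                      chrom = "chr_g002", pos = 637L, alt = "C",
                      frac = 1.0),
                    editing_sites = tibble::tibble(
                      chrom = "chr_g001", pos = 508L, alt = "G",
                      frac = 0.95))
  sim <- simulate_reads(cfg, tr$genome, tr$annotation)
  tab <- tabulate_mismatches(sim$footprints, stops, "footprints_all")
  cls <- classify_calls(elevated_mismatch_test(tab), stops)
  poly <- cls[cls$chrom == "chr_g002", ]
  expect_equal(poly$classification, "stop_to_sense_polymorphism")
  expect_true(poly$exclude_transcript)
  # the editing-driven position is NOT rejected by the editing null
  # (editing plausibly explains the readthrough there)
  ap <- tabulate_mismatches(sim$footprints, stops, "footprints_Apassed")
  ed <- editing_null_test(ap)
  edited <- ed[ed$pos == 508, ]
  expect_gte(edited$n, 10)
  expect_false(edited$editing_rejected)
  # unedited adenines with coverage are rejected (evidence against editing)
  clean <- ed[ed$pos != 508 & ed$n >= 20, ]
  expect_true(all(clean$editing_rejected))
})
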