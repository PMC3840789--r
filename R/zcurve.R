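# Phase-specific Z-curve features and a linear classifier of coding
# potential, plus SNP synonymy tests and the ER-retention motif scan.

ZC_BASES <- c("A", "C", "G", "T")

# (x, y, z) from the four base frequencies: purine/pyrimidine, amino/keto,
# weak/strong axes.
zc_xyz <- function(f) {
  c(x = (f[["A"]] + f[["G"]]) - (f[["C"]] + f[["T"]]),
    y = (f[["A"]] + f[["C"]]) - (f[["G"]] + f[["T"]]),
    z = (f[["A"]] + f[["T"]]) - (f[["G"]] + f[["C"]]))
}

#' Phase-specific Z-curve feature vector (189 components)
#'
#' Computes the 189-variable Z-curve of a nucleotide window: 9 components
#' from phase-specific mononucleotide frequencies, 36 from dinucleotide
#' frequencies conditional on their 1-mer prefix at each phase, and 144
#' from trinucleotide frequencies conditional on their 2-mer prefix. The
#' phase of a k-mer is the codon position of its first base. With
#' `frequencies = "conditional"` (default) the four k-mers sharing a
#' prefix are normalised by the prefix count at that phase; `"joint"`
#' normalises by all k-mers at the phase. Contexts with zero occurrences
#' yield (0, 0, 0). All components lie in [-1, 1].
#'
#' K-mers are counted cyclically (a k-mer extending past the window end
#' wraps to its start), so every phase contributes the same number of
#' k-mers for every k and the features are exactly invariant under
#' in-frame repetition of the window. A trailing partial codon (window
#' length not divisible by 3) is dropped before counting.
#'
#' @param window Nucleotide string over A/C/G/T, at least 81 nt (the
#'   classifier is error-prone below that; the floor is enforced).
#' @param frequencies `"conditional"` or `"joint"`.
#' @return Named numeric vector of length 189.
#' @export
zcurve_features <- function(window, frequencies = c("conditional", "joint")) {
  frequencies <- match.arg(frequencies)
  window <- str_to_upper(window)
  if (nchar(window) < 81) stop("window must be at least 81 nt")
  L <- nchar(window) - nchar(window) %% 3L
  chars <- str_split(str_sub(window, 1L, L), "")[[1]]
  if (!all(chars %in% ZC_BASES)) stop("ambiguity codes are not allowed")
  out <- numeric(0)
  for (k in 1:3) {
    ctxs <- if (k == 1) "" else {
      apply(expand.grid(rep(list(ZC_BASES), k - 1),
                        stringsAsFactors = FALSE)[, rev(seq_len(k - 1)),
                                                  drop = FALSE],
            1, paste, collapse = "")
    }
    for (p in 0:2) {
      starts <- seq.int(p + 1L, L, by = 3L)
      kmer_idx <- outer(starts - 1L, 0:(k - 1L), "+") %% L + 1L
      kmers <- matrix(chars[kmer_idx], nrow = length(starts))
      prefix <- if (k == 1) rep("", length(starts)) else {
        apply(kmers[, seq_len(k - 1L), drop = FALSE], 1, paste,
              collapse = "")
      }
      lastb <- kmers[, k]
      total_p <- length(starts)
      for (ctx in ctxs) {
        sel <- lastb[prefix == ctx]
        cnt <- table(factor(sel, levels = ZC_BASES))
        denom <- if (frequencies == "conditional") sum(cnt) else total_p
        f <- if (denom > 0) as.list(cnt / denom) else
          as.list(setNames(rep(0, 4), ZC_BASES))
        xyz <- if (denom > 0) zc_xyz(f) else c(x = 0, y = 0, z = 0)
        names(xyz) <- paste0("k", k, ".p", p,
                             if (k > 1) paste0(".", ctx) else "",
                             ".", c("x", "y", "z"))
        out <- c(out, xyz)
      }
    }
  }
  stopifnot(length(out) == 189L)
  out
}

#' Train a Z-curve linear classifier
#'
#' Fits a Fisher linear discriminant (via [MASS::lda()]) on Z-curve
#' features of coding (positive) vs non-coding (negative) training
#' windows, reporting the k-fold cross-validated misclassification error
#' before refitting on all data. Constant features are dropped before
#' fitting. The decision is a deterministic affine function of the
#' feature vector.
#'
#' @param positive,negative Character vectors of training windows
#'   (>= 81 nt each; at least 2 per class).
#' @param k_folds Cross-validation folds, default 4.
#' @param seed Seed for the fold assignment and reproducibility.
#' @param frequencies Passed to [zcurve_features()].
#' @return A `zcurve_classifier` object (weights, threshold, cv error).
#' @export
train_zcurve <- function(positive, negative, k_folds = 4L, seed = 1L,
                         frequencies = c("conditional", "joint")) {
  frequencies <- match.arg(frequencies)
  if (length(positive) < 2 || length(negative) < 2) {
    stop("need at least 2 windows per class")
  }
  feats <- function(w) t(vapply(w, zcurve_features, numeric(189),
                                frequencies = frequencies))
  Xp <- feats(positive); Xn <- feats(negative)
  X <- rbind(Xp, Xn)
  y <- factor(c(rep("coding", nrow(Xp)), rep("noncoding", nrow(Xn))),
              levels = c("noncoding", "coding"))
  keep <- apply(X, 2, function(col) {
    var(col[y == "coding"]) > 0 || var(col[y == "noncoding"]) > 0
  })
  if (!any(keep)) stop("degenerate training data: no variable features")
  fit_lda <- function(Xtr, ytr) {
    suppressWarnings(MASS::lda(Xtr, grouping = ytr))
  }
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k_folds), length(y)))
  errs <- map_dbl(seq_len(k_folds), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 1) {
      return(NA_real_)
    }
    m <- fit_lda(X[tr, keep, drop = FALSE], y[tr])
    pred <- stats::predict(m, X[!tr, keep, drop = FALSE])$class
    mean(pred != y[!tr])
  })
  final <- fit_lda(X[, keep, drop = FALSE], y)
  scal <- final$scaling[, 1]
  scores <- X[, keep, drop = FALSE] %*% scal
  mu <- tapply(scores, y, mean)
  # orient so coding scores high
  sgn <- if (mu[["coding"]] >= mu[["noncoding"]]) 1 else -1
  w <- setNames(rep(0, 189), colnames(X))
  w[names(scal)] <- sgn * scal
  threshold <- sgn * mean(mu)
  structure(
    list(weights = w, threshold = threshold,
         cv_error = mean(errs, na.rm = TRUE),
         n_positive = length(positive), n_negative = length(negative),
         k_folds = k_folds, frequencies = frequencies,
         n_features = sum(keep)),
    class = "zcurve_classifier"
  )
}

#' @export
print.zcurve_classifier <- function(x, ...) {
  cat("Z-curve linear classifier (", x$n_features,
      " active of 189 features)\n", sep = "")
  cat("  training: ", x$n_positive, " coding vs ", x$n_negative,
      " non-coding windows\n", sep = "")
  cat("  ", x$k_folds, "-fold CV misclassification error: ",
      sprintf("%.3f", x$cv_error), "\n", sep = "")
  invisible(x)
}

#' Score windows with a Z-curve classifier
#'
#' @param object A `zcurve_classifier`.
#' @param windows Character vector of windows (>= 81 nt).
#' @param ... Unused.
#' @return Tibble with `score` (discriminant value, coding-positive) and
#'   `class`.
#' @export
predict.zcurve_classifier <- function(object, windows, ...) {
  X <- t(vapply(windows, zcurve_features, numeric(189),
                frequencies = object$frequencies))
  s <- drop(X %*% object$weights)
  tibble(score = s,
         class = if_else(s >= object$threshold, "coding", "noncoding"))
}

#' @export
tidy.zcurve_classifier <- function(x, ...) {
  tibble(term = names(x$weights), estimate = unname(x$weights))
}

#' @export
glance.zcurve_classifier <- function(x, ...) {
  tibble(cv_error = x$cv_error, n_positive = x$n_positive,
         n_negative = x$n_negative, k_folds = x$k_folds,
         n_features = x$n_features, threshold = x$threshold)
}

#' Serialise / restore a Z-curve classifier as a flat text table
#'
#' @param model A `zcurve_classifier`.
#' @param path File path.
#' @return `read_zcurve_model` returns the model; the writer returns the
#'   path invisibly.
#' @export
write_zcurve_model <- function(model, path) {
  hdr <- sprintf("# threshold\t%.17g\n# cv_error\t%.17g\n# frequencies\t%s",
                 model$threshold, model$cv_error, model$frequencies)
  writeLines(c(hdr, paste(names(model$weights),
                          sprintf("%.17g", model$weights), sep = "\t")),
             path)
  invisible(path)
}

#' @rdname write_zcurve_model
#' @export
read_zcurve_model <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  kv <- str_split(sub("^# ", "", meta), "\t")
  meta_l <- setNames(map_chr(kv, 2), map_chr(kv, 1))
  parts <- str_split(body, "\t")
  w <- setNames(as.numeric(map_chr(parts, 2)), map_chr(parts, 1))
  structure(list(weights = w, threshold = as.numeric(meta_l[["threshold"]]),
                 cv_error = as.numeric(meta_l[["cv_error"]]),
                 frequencies = meta_l[["frequencies"]],
                 n_features = sum(w != 0), n_positive = NA_integer_,
                 n_negative = NA_integer_, k_folds = NA_integer_),
            class = "zcurve_classifier")
}

#' Score region groups and compare them
#'
#' Draws one seeded random 81-nt window from every region sequence of at
#' least 81 nt (shorter regions are excluded), scores the windows with the
#' classifier, and compares every pair of groups with the Mann-Whitney
#' rank-sum test.
#'
#' @param model A `zcurve_classifier`.
#' @param regions Tibble with `group` and `seq` columns (one region per
#'   row), or a named list of character vectors.
#' @param window Window size, default 81.
#' @param avoid_last Exclude the last `avoid_last` bases of each sequence
#'   from window sampling (e.g. 50 to dodge polyadenylation signals).
#' @param seed Seed for window sampling.
#' @return A `zcurve_scores` list: `scores` tibble, `medians`, `tests`.
#' @export
score_extensions <- function(model, regions, window = 81L, avoid_last = 0L,
                             seed = 1L) {
  if (!is_tibble(regions)) {
    regions <- bind_rows(map2(names(regions), regions, function(g, s) {
      tibble(group = g, seq = s)
    }))
  }
  set.seed(seed)
  usable <- filter(regions, nchar(.data$seq) - avoid_last >= window)
  if (nrow(usable) == 0) stop("no region long enough to score")
  starts <- map_int(nchar(usable$seq), function(L) {
    sample.int(L - avoid_last - window + 1L, 1)
  })
  wins <- str_sub(usable$seq, starts, starts + window - 1L)
  scored <- bind_cols(select(usable, "group"),
                      predict(model, wins))
  med <- scored |>
    group_by(.data$group) |>
    summarise(median_score = median(.data$score), n = n(),
              .groups = "drop")
  groups <- unique(scored$group)
  tests <- if (length(groups) >= 2) {
    prs <- combn(groups, 2)
    bind_rows(map(seq_len(ncol(prs)), function(i) {
      a <- scored$score[scored$group == prs[1, i]]
      b <- scored$score[scored$group == prs[2, i]]
      rs <- rank_sum(a, b)
      tibble(group1 = prs[1, i], group2 = prs[2, i], U = rs$U, p = rs$p)
    }))
  } else {
    tibble(group1 = character(0))
  }
  structure(list(scores = scored, medians = med, tests = tests),
            class = "zcurve_scores")
}

#' SNP synonymy by in-frame translation
#'
#' For SNPs annotated with their host codon (mRNA sense) and in-codon
#' offset, determines whether the substitution is synonymous under the
#' standard genetic code, and compares the synonymous proportion between
#' region pairs with one-sided Fisher's exact tests (testing greater
#' synonymy in the first region).
#'
#' @param snps Tibble with `region`, `codon`, `codon_offset` (1-3),
#'   `alt` (mRNA sense). SNPs whose codon is NA (no defined frame) are
#'   excluded and tallied.
#' @return List: `snps` (with `synonymous`), `by_region` (counts and
#'   proportions), `tests` (pairwise one-sided Fisher), `n_excluded`.
#' @export
snp_synonymy <- function(snps) {
  ok <- filter(snps, !is.na(.data$codon))
  n_excluded <- nrow(snps) - nrow(ok)
  code <- Biostrings::GENETIC_CODE
  ok$synonymous <- map_lgl(seq_len(nrow(ok)), function(i) {
    cod <- ok$codon[i]
    mut <- cod
    str_sub(mut, ok$codon_offset[i], ok$codon_offset[i]) <- ok$alt[i]
    code[[cod]] == code[[mut]]
  })
  by_region <- ok |>
    group_by(.data$region) |>
    summarise(syn = sum(.data$synonymous), nonsyn = sum(!.data$synonymous),
              proportion_synonymous = mean(.data$synonymous),
              .groups = "drop")
  groups <- by_region$region
  tests <- if (length(groups) >= 2) {
    prs <- combn(groups, 2)
    bind_rows(map(seq_len(ncol(prs)), function(i) {
      a <- by_region[by_region$region == prs[1, i], ]
      b <- by_region[by_region$region == prs[2, i], ]
      p <- fisher_exact(matrix(c(a$syn, a$nonsyn, b$syn, b$nonsyn),
                               nrow = 2, byrow = TRUE), "greater")
      tibble(region1 = prs[1, i], region2 = prs[2, i], p = p)
    }))
  } else {
    tibble(region1 = character(0))
  }
  list(snps = ok, by_region = by_region, tests = tests,
       n_excluded = n_excluded)
}

#' Annotate genomic SNPs with host codon and region
#'
#' Maps SNPs onto CDS and candidate-extension/distal frames so
#' [snp_synonymy()] can evaluate them. SNPs outside any framed region get
#' NA codons.
#'
#' @param snps Tibble with `chrom`, `pos` (0-based), `alt`.
#' @param annotation Exon-level annotation tibble.
#' @param genome Named character vector of chromosome sequences.
#' @param candidates Optional candidate tibble (adds extension and
#'   distal3UTR regions).
#' @return `snps` with `region`, `codon`, `codon_offset` and `alt` in
#'   mRNA sense.
#' @export
annotate_snps <- function(snps, annotation, genome, candidates = NULL) {
  frames <- region_frames(annotation, candidates)
  frames <- distinct(frames, .data$chrom, .data$pos, .keep_all = TRUE)
  j <- left_join(snps, frames, by = c("chrom", "pos"))
  j$codon <- NA_character_
  j$codon_offset <- NA_integer_
  for (i in which(!is.na(j$frame))) {
    sgn <- if (j$strand[i] == "+") 1L else -1L
    first <- j$pos[i] - sgn * j$frame[i]
    cpos <- first + sgn * (0:2)
    bases <- map_chr(cpos, function(p) {
      b <- str_sub(genome[[j$chrom[i]]], p + 1L, p + 1L)
      if (j$strand[i] == "-") COMPLEMENT[[b]] else b
    })
    j$codon[i] <- paste(bases, collapse = "")
    j$codon_offset[i] <- j$frame[i] + 1L
    if (j$strand[i] == "-") j$alt[i] <- COMPLEMENT[[j$alt[i]]]
  }
  j
}

#' Scan peptides for a C-terminal ER retention signal
#'
#' A hit is a C-terminus matching the consensus `[KH]DEL`.
#'
#' @param peptides Character vector of peptide sequences.
#' @return Logical vector of hits.
#' @export
er_retention_scan <- function(peptides) {
  str_detect(str_to_upper(peptides), "[KH]DEL$")
}
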