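# Iterative marker/sample quality control and LD summaries.

#' Quality-control thresholds
#'
#' Defaults follow standard practice for dense bovine SNP panels: GenCall
#' score > 0.70, MAF >= 0.02, Hardy-Weinberg p >= 1e-5, marker call rate
#' >= 0.98, sample call rate >= 0.90, and LD pruning of pairs with
#' r-squared >= 0.995 within 100-SNP windows.
#'
#' @param maf,hwe_p,marker_callrate,sample_callrate,gencall Filter thresholds.
#' @param ld_window Window size (consecutive SNPs) for LD pruning.
#' @param ld_r2 r-squared threshold above which one of a pair is pruned.
#' @return A named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf = 0.02, hwe_p = 1e-5, marker_callrate = 0.98,
                          sample_callrate = 0.90, gencall = 0.70,
                          ld_window = 100, ld_r2 = 0.995) {
  structure(list(maf = maf, hwe_p = hwe_p, marker_callrate = marker_callrate,
                 sample_callrate = sample_callrate, gencall = gencall,
                 ld_window = check_count(ld_window, "ld_window"),
                 ld_r2 = ld_r2),
            class = "qc_thresholds")
}

#' Minor allele frequency of a genotype column
#'
#' @param codes_column Vector of 0/1/2 codes (NA = missing).
#' @return `min(f, 1 - f)` where `f` is the B-allele frequency over observed
#'   genotypes; `NA` (with a warning) if nothing is observed.
#' @export
compute_maf <- function(codes_column) {
  obs <- codes_column[!is.na(codes_column)]
  if (!length(obs)) {
    warning("all genotypes missing; MAF undefined")
    return(NA_real_)
  }
  f <- sum(obs) / (2 * length(obs))
  min(f, 1 - f)
}

#' Hardy-Weinberg equilibrium test for one marker
#'
#' One-degree-of-freedom chi-squared goodness-of-fit of the observed (AA, AB,
#' BB) counts against the expected proportions \eqn{(1-\hat p)^2,
#' 2\hat p(1-\hat p), \hat p^2}. Monomorphic columns return p = 1 by
#' convention (they are handled by the MAF filter).
#'
#' @param codes_column Vector of 0/1/2 codes (NA = missing).
#' @return The p-value; `NA` with a warning when nothing is observed.
#' @export
hwe_test <- function(codes_column) {
  obs <- codes_column[!is.na(codes_column)]
  n <- length(obs)
  if (!n) {
    warning("all genotypes missing; HWE test undefined")
    return(NA_real_)
  }
  counts <- tabulate(obs + 1L, nbins = 3L)
  f <- (counts[2L] + 2 * counts[3L]) / (2 * n)
  if (f <= 0 || f >= 1) return(1)
  expected <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
  chi2 <- sum((counts - expected)^2 / expected)
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Per-marker and per-sample call rates
#'
#' @param genotypes A [geno_matrix()] or dosage matrix.
#' @return List with `marker` (fraction non-missing per column) and `sample`
#'   (per row), both named.
#' @export
call_rates <- function(genotypes) {
  codes <- as_geno_codes(genotypes)
  ok <- !is.na(codes)
  list(marker = colMeans(ok), sample = rowMeans(ok))
}

#' Squared Pearson correlation between two genotype columns
#'
#' Computed over jointly observed entries; symmetric and invariant to allele
#' relabelling (g -> 2 - g). Pairs with fewer than two joint observations or
#' zero variance return `NA` (treated as r2 = 0 by the LD pruner).
#'
#' @param col_a,col_b Genotype code vectors of equal length.
#' @return Squared correlation in `[0, 1]`, or `NA`.
#' @export
pairwise_r2 <- function(col_a, col_b) {
  ok <- !is.na(col_a) & !is.na(col_b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- col_a[ok]; b <- col_b[ok]
  if (var(a) == 0 || var(b) == 0) return(NA_real_)
  cor(a, b)^2
}

# r2 matrix for a block of columns; NAs (no variance) become 0
block_r2 <- function(codes) {
  suppressWarnings(r <- cor(codes, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r^2
}

#' Prune high-LD marker pairs within windows
#'
#' Within each window of `window` consecutive markers per chromosome
#' (non-overlapping blocks; markers must be sorted by chromosome and
#' position), offending pairs with r-squared >= `r2_max` are resolved by
#' removing the lower-MAF member; MAF ties drop the later-positioned marker.
#' After pruning, every surviving within-window pair is below the threshold.
#'
#' @param genotypes A [geno_matrix()].
#' @param window Window size in SNPs; `window = 1` disables pruning.
#' @param r2_max r-squared threshold.
#' @return Character vector of marker ids to remove.
#' @export
prune_ld_windows <- function(genotypes, window = 100, r2_max = 0.995) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  window <- check_count(window, "window")
  codes <- genotypes$codes
  markers <- genotypes$markers
  removed <- character(0)
  if (window < 2L) return(removed)
  for (chr in unique(markers$chrom)) {
    jj <- which(markers$chrom == chr)
    jj <- jj[order(markers$pos[jj])]
    starts <- seq(1L, length(jj), by = window)
    for (s in starts) {
      win <- jj[s:min(s + window - 1L, length(jj))]
      if (length(win) < 2L) next
      r2 <- block_r2(codes[, win, drop = FALSE])
      maf <- vapply(win, function(j) compute_maf(codes[, j]), numeric(1))
      alive <- rep(TRUE, length(win))
      repeat {
        idx <- which(alive)
        off <- which(r2[idx, idx, drop = FALSE] >= r2_max &
                       upper.tri(r2[idx, idx, drop = FALSE]), arr.ind = TRUE)
        if (!nrow(off)) break
        a <- idx[off[1L, 1L]]; b <- idx[off[1L, 2L]]
        drop_j <- if (is.na(maf[a]) || is.na(maf[b])) max(a, b)
          else if (maf[a] < maf[b]) a
          else if (maf[b] < maf[a]) b
          else max(a, b)  # tie: later-positioned marker
        alive[drop_j] <- FALSE
      }
      removed <- c(removed, markers$id[win[!alive]])
    }
  }
  removed
}

#' Iterative genotype quality control
#'
#' Applies, in order within each iteration: non-autosomal removal, GenCall
#' score, duplicate-position pairs (both members removed), MAF,
#' Hardy-Weinberg, marker call rate, windowed LD pruning, and sample call
#' rate. All statistics are recomputed on the surviving matrix each
#' iteration, and iterations repeat until nothing more is removed (a
#' fixpoint). Each removed item records the first filter that triggered it.
#'
#' @param genotypes A [geno_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @param verbose Log one line per iteration via `message()`.
#' @return List with `genotypes` (filtered matrix) and `report`
#'   (class `qc_report`: `removed_markers`, `removed_samples`, `iterations`,
#'   `thresholds`).
#' @export
iterative_qc <- function(genotypes, thresholds = qc_thresholds(),
                         verbose = FALSE) {
  stopifnot(inherits(genotypes, "geno_matrix"),
            inherits(thresholds, "qc_thresholds"))
  g <- genotypes
  rm_mark <- list(); rm_samp <- list()
  iteration <- 0L
  note_m <- function(ids, reason) {
    if (length(ids))
      rm_mark[[length(rm_mark) + 1L]] <<-
        data.frame(id = ids, type = "marker", reason = reason,
                   iteration = iteration, stringsAsFactors = FALSE)
    length(ids) > 0L
  }
  repeat {
    iteration <- iteration + 1L
    changed <- FALSE
    drop_markers <- function(ids, reason) {
      if (note_m(ids, reason)) {
        g <<- g[, setdiff(g$markers$id, ids)]
        changed <<- TRUE
      }
    }
    m <- g$markers
    drop_markers(m$id[!grepl("^[0-9]+$", m$chrom)], "nonautosomal")
    m <- g$markers
    drop_markers(m$id[m$gencall <= thresholds$gencall], "gencall")
    m <- g$markers
    key <- paste(m$chrom, m$pos)
    drop_markers(m$id[key %in% key[duplicated(key)]], "dup_position")
    if (ncol(g$codes) == 0L || nrow(g$codes) == 0L) break
    maf <- apply(g$codes, 2L, compute_maf)
    drop_markers(g$markers$id[!is.na(maf) & maf < thresholds$maf], "maf")
    if (ncol(g$codes)) {
      hwe <- apply(g$codes, 2L, hwe_test)
      drop_markers(g$markers$id[!is.na(hwe) & hwe < thresholds$hwe_p], "hwe")
    }
    if (ncol(g$codes)) {
      cr <- call_rates(g)
      drop_markers(g$markers$id[cr$marker < thresholds$marker_callrate],
                   "marker_callrate")
    }
    if (ncol(g$codes) >= 2L)
      drop_markers(prune_ld_windows(g, thresholds$ld_window, thresholds$ld_r2),
                   "ld_prune")
    if (ncol(g$codes)) {
      cr <- call_rates(g)
      bad <- g$samples[cr$sample < thresholds$sample_callrate]
      if (length(bad)) {
        rm_samp[[length(rm_samp) + 1L]] <-
          data.frame(id = bad, type = "sample", reason = "sample_callrate",
                     iteration = iteration, stringsAsFactors = FALSE)
        g <- g[setdiff(g$samples, bad), ]
        changed <- TRUE
      }
    }
    if (verbose) {
      nm <- sum(vapply(rm_mark, nrow, 0L)[
        vapply(rm_mark, function(d) d$iteration[1L], 0L) == iteration])
      message(sprintf("QC iteration %d: removed %d markers; %d markers x %d samples remain",
                      iteration, nm, ncol(g$codes), nrow(g$codes)))
    }
    if (!changed || ncol(g$codes) == 0L || nrow(g$codes) == 0L) break
  }
  empty_df <- data.frame(id = character(0), type = character(0),
                         reason = character(0), iteration = integer(0),
                         stringsAsFactors = FALSE)
  report <- structure(
    list(removed_markers = if (length(rm_mark)) do.call(rbind, rm_mark)
                           else empty_df,
         removed_samples = if (length(rm_samp)) do.call(rbind, rm_samp)
                           else empty_df,
         iterations = iteration, thresholds = thresholds),
    class = "qc_report")
  if (ncol(g$codes) == 0L || nrow(g$codes) == 0L)
    warning("quality control removed everything")
  list(genotypes = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d iterations, %d markers and %d samples removed\n",
              x$iterations, nrow(x$removed_markers), nrow(x$removed_samples)))
  if (nrow(x$removed_markers)) {
    tab <- table(x$removed_markers$reason)
    cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write a QC report as TSV
#'
#' One row per removed item: `item`, `type`, `reason`, `iteration`.
#'
#' @param report A `qc_report` from [iterative_qc()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  out <- rbind(report$removed_markers, report$removed_samples)
  names(out)[1L] <- "item"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean adjacent-marker linkage disequilibrium
#'
#' Mean [pairwise_r2()] over all physically adjacent marker pairs within
#' chromosomes — the standard summary of whether a panel is dense enough for
#' markers to tag QTL.
#'
#' @param genotypes A [geno_matrix()].
#' @return Mean r-squared; `NA` with a warning if no chromosome has two
#'   markers.
#' @export
adjacent_ld_summary <- function(genotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  codes <- genotypes$codes
  markers <- genotypes$markers
  vals <- numeric(0)
  for (chr in unique(markers$chrom)) {
    jj <- which(markers$chrom == chr)
    jj <- jj[order(markers$pos[jj])]
    if (length(jj) < 2L) next
    r2 <- vapply(seq_len(length(jj) - 1L), function(k)
      pairwise_r2(codes[, jj[k]], codes[, jj[k + 1L]]), numeric(1))
    vals <- c(vals, r2)
  }
  if (!length(vals)) {
    warning("fewer than two markers on every chromosome; LD undefined")
    return(NA_real_)
  }
  mean(vals, na.rm = TRUE)
}
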