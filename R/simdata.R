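# Synthetic half-sib populations: founder haplotypes with block LD, paternal
# half-sib pedigrees, gene dropping, trait simulation and planted QC defects.

#' Simulate founder haplotypes with block linkage disequilibrium
#'
#' Generates `2 * n_founders` binary haplotypes at evenly spaced markers. LD is
#' produced by a block Gaussian copula: within each `ld_block_len`-cM block the
#' latent normals follow an AR(1) with correlation `ld_rho` between adjacent
#' markers, and blocks are independent. Thresholding the latent variable at the
#' normal quantile of the drawn allele frequency yields correlated binary
#' alleles whose adjacent-marker genotype r-squared sits near 0.3 under the
#' defaults, the level typical of dense bovine SNP panels. `ld_block_len = 0`
#' puts every marker in its own block (linkage equilibrium).
#'
#' @param n_founders Number of founder individuals (>= 1).
#' @param n_chrom Number of chromosomes.
#' @param markers_per_chrom Markers per chromosome.
#' @param chrom_len_cm Chromosome map length in centimorgans.
#' @param ld_block_len LD block length in centimorgans (0 = no LD).
#' @param ld_rho Latent AR(1) correlation between adjacent markers in a block.
#' @param freq_range Range from which founder B-allele frequencies are drawn
#'   uniformly; keeps markers away from fixation.
#' @param seed Integer seed; identical seeds give identical panels.
#' @return An object of class `haplotype_panel`: list with `haplotypes`
#'   (`2*n_founders x p` 0/1 matrix), `map` (marker, chrom, cm, pos) and
#'   `freq` (drawn allele frequencies).
#' @export
simulate_founder_haplotypes <- function(n_founders, n_chrom = 10,
                                        markers_per_chrom = 500,
                                        chrom_len_cm = 100,
                                        ld_block_len = 5, ld_rho = 0.93,
                                        freq_range = c(0.1, 0.9),
                                        seed = NULL) {
  n_founders <- check_count(n_founders, "n_founders")
  n_chrom <- check_count(n_chrom, "n_chrom")
  markers_per_chrom <- check_count(markers_per_chrom, "markers_per_chrom")
  if (chrom_len_cm <= 0) stop_arg("`chrom_len_cm` must be positive")
  if (ld_block_len < 0) stop_arg("`ld_block_len` must be >= 0")
  ld_rho <- check_proportion(ld_rho, "ld_rho")
  with_seed(seed, {
    p <- n_chrom * markers_per_chrom
    nh <- 2L * n_founders
    chrom <- rep(seq_len(n_chrom), each = markers_per_chrom)
    cm <- rep((seq_len(markers_per_chrom) - 0.5) *
                chrom_len_cm / markers_per_chrom, times = n_chrom)
    block <- if (ld_block_len > 0) floor(cm / ld_block_len) else seq_len(p)
    freq <- runif(p, freq_range[1L], freq_range[2L])
    z <- matrix(0, nh, p)
    z[, 1L] <- rnorm(nh)
    sds <- sqrt(1 - ld_rho^2)
    for (j in 2L:p) {
      new_block <- chrom[j] != chrom[j - 1L] || block[j] != block[j - 1L]
      z[, j] <- if (new_block) rnorm(nh) else
        ld_rho * z[, j - 1L] + sds * rnorm(nh)
    }
    hap <- matrix(0L, nh, p)
    hap[sweep(z, 2L, qnorm(freq), "<")] <- 1L
    # guarantee polymorphism among founders
    cs <- colSums(hap)
    for (j in which(cs == 0L | cs == nh)) {
      hap[sample.int(nh, 1L), j] <- 1L - hap[1L, j]
    }
    map <- data.frame(marker = sprintf("snp%d_%d", chrom,
                                       rep(seq_len(markers_per_chrom), n_chrom)),
                      chrom = chrom, cm = cm, pos = round(cm * 1e6),
                      stringsAsFactors = FALSE)
    structure(list(haplotypes = hap, map = map, freq = freq),
              class = "haplotype_panel")
  })
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d markers on %d chromosomes\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              length(unique(x$map$chrom))))
  invisible(x)
}

#' Simulate a paternal half-sib pedigree
#'
#' Founder sires and dams with unknown parents; each offspring gets one sire
#' (sampled uniformly with replacement, so sires found half-sib families) and
#' one dam. When `n_dams >= n_offspring` every dam is used at most once;
#' otherwise shuffled dams are recycled so reuse is as rare as possible.
#'
#' @param n_sires,n_dams,n_offspring Counts (>= 1).
#' @param seed Integer seed.
#' @return `data.frame` with columns `id`, `sire`, `dam` ("0" = unknown),
#'   founders first, of class `c("pedigree", "data.frame")`.
#' @export
simulate_pedigree <- function(n_sires, n_dams, n_offspring, seed = NULL) {
  n_sires <- check_count(n_sires, "n_sires")
  n_dams <- check_count(n_dams, "n_dams")
  n_offspring <- check_count(n_offspring, "n_offspring")
  with_seed(seed, {
    sires <- sprintf("S%04d", seq_len(n_sires))
    dams <- sprintf("D%04d", seq_len(n_dams))
    off <- sprintf("O%04d", seq_len(n_offspring))
    sire_of <- sample(sires, n_offspring, replace = TRUE)
    dam_of <- if (n_dams >= n_offspring) sample(dams, n_offspring)
              else sample(rep(sample(dams), length.out = n_offspring))
    ped <- data.frame(id = c(sires, dams, off),
                      sire = c(rep("0", n_sires + n_dams), sire_of),
                      dam = c(rep("0", n_sires + n_dams), dam_of),
                      stringsAsFactors = FALSE)
    class(ped) <- c("pedigree", "data.frame")
    ped
  })
}

#' Gene-drop genotypes through a pedigree
#'
#' Founders receive consecutive haplotype pairs from `panel` (in pedigree
#' order); every non-founder inherits one recombinant gamete from each parent.
#' Recombination follows Haldane's model: the probability of a crossover
#' between adjacent markers `d` cM apart is `0.5 * (1 - exp(-2 * d *
#' recomb_rate))`, with `recomb_rate` the per-cM recombination density (0.01
#' gives the standard 1 cM = 1% map calibration).
#'
#' @param panel A [simulate_founder_haplotypes()] panel; it must contain at
#'   least two haplotypes per pedigree founder.
#' @param pedigree A pedigree `data.frame` (id, sire, dam; "0" unknown).
#' @param recomb_rate Recombination probability per cM.
#' @param missing_rate Probability that any genotype call is set missing.
#' @param seed Integer seed.
#' @param animals Ids to return genotypes for (default: all pedigree members).
#' @return A [geno_matrix()] with 0/1/2 codes (B-allele dosage).
#' @export
drop_genotypes <- function(panel, pedigree, recomb_rate = 0.01,
                           missing_rate = 0, seed = NULL,
                           animals = pedigree$id) {
  stopifnot(inherits(panel, "haplotype_panel"))
  missing_rate <- check_proportion(missing_rate, "missing_rate")
  if (recomb_rate < 0) stop_arg("`recomb_rate` must be >= 0")
  ped <- order_pedigree(pedigree)
  founder <- ped$sire == "0" & ped$dam == "0"
  if (2L * sum(founder) > nrow(panel$haplotypes))
    stop_arg("panel has fewer than two haplotypes per pedigree founder ",
             "(configuration error)")
  p <- ncol(panel$haplotypes)
  n <- nrow(ped)
  with_seed(seed, {
    # crossover probabilities between consecutive markers; chromosome starts
    # get 0.5 so each chromosome picks its initial strand at random
    d <- c(0, diff(panel$map$cm))
    rvec <- 0.5 * (1 - exp(-2 * d * recomb_rate))
    rvec[c(TRUE, diff(panel$map$chrom) != 0)] <- 0.5
    H1 <- matrix(0L, n, p)
    H2 <- matrix(0L, n, p)
    idx <- setNames(seq_len(n), ped$id)
    fi <- 0L
    for (i in seq_len(n)) {
      if (founder[i]) {
        fi <- fi + 1L
        H1[i, ] <- panel$haplotypes[2L * fi - 1L, ]
        H2[i, ] <- panel$haplotypes[2L * fi, ]
      } else {
        for (side in 1:2) {
          par <- idx[[ped[[c("sire", "dam")[side]]][i]]]
          strand <- cumsum(runif(p) < rvec) %% 2L
          gam <- ifelse(strand == 0L, H1[par, ], H2[par, ])
          if (side == 1L) H1[i, ] <- gam else H2[i, ] <- gam
        }
      }
    }
    codes <- H1 + H2
    rownames(codes) <- ped$id
    keep <- match(animals, ped$id)
    if (anyNA(keep)) stop_arg("`animals` contains ids absent from the pedigree")
    codes <- codes[keep, , drop = FALSE]
    if (missing_rate > 0)
      codes[runif(length(codes)) < missing_rate] <- NA
    markers <- data.frame(id = panel$map$marker, chrom = panel$map$chrom,
                          pos = panel$map$pos, cm = panel$map$cm,
                          stringsAsFactors = FALSE)
    geno_matrix(codes, markers, animals)
  })
}

#' Trait configuration for phenotype simulation
#'
#' Bundles the generative parameters of a polygenic trait. Presets mirror the
#' three carcass traits commonly studied in Nellore steers: rib eye area
#' (`"REA"`, h2 = 0.20), backfat thickness (`"BFT"`, h2 = 0.08) and hot
#' carcass weight (`"HCW"`, h2 = 0.17), with phenotypic scales matching their
#' reported variance components.
#'
#' @param trait Optional preset name ("REA", "BFT", "HCW").
#' @param n_qtl Number of QTL drawn from the genotyped markers.
#' @param h2 Narrow-sense heritability in (0, 1).
#' @param cg_count Number of contemporary groups (default ~ n/12 at use time).
#' @param cg_sd SD of contemporary-group effects (trait units).
#' @param age_slope Linear effect of age at slaughter (units per day).
#' @param mean Trait mean.
#' @param sigma_p Target phenotypic SD (genetic + residual; trait units).
#' @return A list of class `trait_config`.
#' @export
trait_config <- function(trait = NULL, n_qtl = 300, h2 = 0.20,
                         cg_count = NULL, cg_sd = NULL, age_slope = NULL,
                         mean = 0, sigma_p = 1) {
  if (!is.null(trait)) {
    preset <- switch(match.arg(trait, c("REA", "BFT", "HCW")),
      REA = list(h2 = 0.20, mean = 68.6, sigma_p = sqrt(10.88 + 41.71),
                 cg_sd = 4.6, age_slope = 0.02),
      BFT = list(h2 = 0.08, mean = 4.84, sigma_p = sqrt(0.30 + 3.31),
                 cg_sd = 1.7, age_slope = 0.005),
      HCW = list(h2 = 0.17, mean = 277.9, sigma_p = sqrt(47.80 + 238.25),
                 cg_sd = 16, age_slope = 0.15))
    h2 <- preset$h2; mean <- preset$mean; sigma_p <- preset$sigma_p
    if (is.null(cg_sd)) cg_sd <- preset$cg_sd
    if (is.null(age_slope)) age_slope <- preset$age_slope
  }
  if (is.null(cg_sd)) cg_sd <- 0.5 * sigma_p
  if (is.null(age_slope)) age_slope <- 0
  h2 <- check_proportion(h2, "h2", open = TRUE)
  n_qtl <- check_count(n_qtl, "n_qtl")
  structure(list(trait = trait, n_qtl = n_qtl, h2 = h2, cg_count = cg_count,
                 cg_sd = cg_sd, age_slope = age_slope, mean = mean,
                 sigma_p = sigma_p),
            class = "trait_config")
}

#' Simulate phenotypes with known true breeding values
#'
#' QTL are sampled from the genotyped markers with i.i.d. normal
#' allele-substitution effects; the true breeding value is the centered QTL
#' dosage score, and the residual variance is scaled so that
#' `var(tbv) / (var(tbv) + var(e))` equals `config$h2`. Phenotype =
#' mean + contemporary-group effect + age slope x (age - 731.9) + TBV +
#' residual. Ages are drawn from N(731.9, 83) days truncated at three SD, and
#' contemporary-group labels are assigned so every group keeps at least three
#' animals.
#'
#' @param genotypes [geno_matrix()] of the animals to phenotype.
#' @param pedigree Pedigree containing those animals.
#' @param config A [trait_config()].
#' @param seed Integer seed.
#' @return List with `phenotypes` (`data.frame`: animal, value, cg, age, herd)
#'   and `truth` (list: tbv, qtl_ids, qtl_effects, true_h2, realized_h2,
#'   cg_effects, beta_age, sigma_e2).
#' @export
simulate_phenotypes <- function(genotypes, pedigree, config = trait_config(),
                                seed = NULL) {
  stopifnot(inherits(config, "trait_config"))
  codes <- as_geno_codes(genotypes)
  n <- nrow(codes)
  if (config$n_qtl > ncol(codes))
    stop_arg("`n_qtl` exceeds the number of markers")
  with_seed(seed, {
    qtl <- sort(sample.int(ncol(codes), config$n_qtl))
    alpha <- rnorm(config$n_qtl)
    wq <- codes[, qtl, drop = FALSE]
    if (anyNA(wq)) wq <- impute_genotypes(wq)
    tbv <- drop(wq %*% alpha)
    tbv <- tbv - mean(tbv)
    v_tbv <- var(tbv)
    if (v_tbv > 0) {
      scale <- config$h2 * config$sigma_p^2 / v_tbv
      alpha <- alpha * sqrt(scale)
      tbv <- tbv * sqrt(scale)
      v_tbv <- var(tbv)
      sigma_e2 <- v_tbv * (1 - config$h2) / config$h2
    } else {
      sigma_e2 <- (1 - config$h2) * config$sigma_p^2
    }
    e <- rnorm(n, 0, sqrt(sigma_e2))
    cg_count <- config$cg_count
    if (is.null(cg_count)) cg_count <- max(1L, round(n / 12))
    cg_count <- check_count(cg_count, "cg_count")
    if (n < 3L * cg_count)
      stop_arg("need at least three animals per contemporary group")
    cg <- sample(rep(seq_len(cg_count), length.out = n))
    cg_eff <- rnorm(cg_count, 0, config$cg_sd)
    age <- rnorm(n, 731.9, 83)
    while (any(bad <- abs(age - 731.9) > 3 * 83))
      age[bad] <- rnorm(sum(bad), 731.9, 83)
    value <- config$mean + cg_eff[cg] + config$age_slope * (age - 731.9) +
      tbv + e
    ids <- rownames(codes)
    phen <- data.frame(animal = ids, value = value,
                       cg = sprintf("CG%03d", cg), age = age,
                       herd = sprintf("H%02d", ((cg - 1L) %% 10L) + 1L),
                       stringsAsFactors = FALSE)
    truth <- list(tbv = setNames(tbv, ids),
                  qtl_ids = colnames(codes)[qtl],
                  qtl_effects = alpha, true_h2 = config$h2,
                  realized_h2 = v_tbv / (v_tbv + sigma_e2),
                  cg_effects = cg_eff, beta_age = config$age_slope,
                  sigma_e2 = sigma_e2)
    list(phenotypes = phen, truth = truth)
  })
}

#' Defect rates for planted quality-control offenders
#'
#' Each rate is the fraction of markers (or samples, for `sample_callrate`)
#' that receive the corresponding defect: near-monomorphic columns
#' (MAF ~ 0.01), heterozygote-free columns violating Hardy-Weinberg,
#' markers with ~4% missing calls, duplicated-position pairs, duplicated
#' columns (r-squared = 1, caught by LD pruning), GenCall scores below 0.70,
#' non-autosomal reassignment, and individuals with ~15% missing calls.
#'
#' @param maf,hwe,marker_callrate,dup_position,dup_column,gencall,nonautosomal
#'   Marker defect rates in `[0, 1]`.
#' @param sample_callrate Sample defect rate in `[0, 1]`.
#' @return A named list of class `defect_spec`.
#' @export
defect_spec <- function(maf = 0, hwe = 0, marker_callrate = 0,
                        dup_position = 0, dup_column = 0, gencall = 0,
                        nonautosomal = 0, sample_callrate = 0) {
  spec <- list(maf = maf, hwe = hwe, marker_callrate = marker_callrate,
               dup_position = dup_position, dup_column = dup_column,
               gencall = gencall, nonautosomal = nonautosomal,
               sample_callrate = sample_callrate)
  for (nm in names(spec)) check_proportion(spec[[nm]], nm)
  structure(spec, class = "defect_spec")
}

#' Plant quality-control defects into a genotype matrix
#'
#' Overwrites randomly chosen clean markers (disjoint across defect classes)
#' with the offender patterns of [defect_spec()]. The planted items are
#' recorded in the `"planted"` attribute (`data.frame`: id, class, expected
#' removal reason) so QC tests can assert an exact round trip.
#'
#' @param genotypes A [geno_matrix()].
#' @param spec A [defect_spec()]; all-zero rates return the input unchanged.
#' @param seed Integer seed.
#' @return The modified `geno_matrix` with a `"planted"` attribute.
#' @export
inject_qc_defects <- function(genotypes, spec = defect_spec(), seed = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(spec, "defect_spec"))
  codes <- genotypes$codes
  markers <- genotypes$markers
  n <- nrow(codes); p <- ncol(codes)
  n_of <- function(rate, total) min(total, round(rate * total))
  with_seed(seed, {
    planted <- list()
    pool <- seq_len(p)
    # within-chromosome rank, used to keep planted LD pairs away from the
    # boundaries of the default 100-SNP pruning windows (upstream removals
    # shift ranks a little; the margin absorbs that)
    chrom_rank <- stats::ave(seq_len(p), markers$chrom, FUN = seq_along)
    take <- function(k, pairs = FALSE, window_safe = FALSE) {
      # draw marker (or adjacent-pair) indices without reusing markers
      if (!pairs) {
        sel <- sort(sample(pool, k))
        pool <<- setdiff(pool, sel)
        return(sel)
      }
      firsts <- integer(0)
      cand <- pool[pool < p & (pool + 1L) %in% pool &
                     markers$chrom[pool] ==
                       markers$chrom[pmin(pool + 1L, p)]]
      if (window_safe) {
        # keep pairs in the interior of each chromosome's first pruning
        # window so that moderate upstream removals cannot split them
        cand <- cand[chrom_rank[cand] >= 21L & chrom_rank[cand] <= 78L]
      }
      while (length(firsts) < k && length(cand)) {
        j <- sample(cand, 1L)
        firsts <- c(firsts, j)
        pool <<- setdiff(pool, c(j, j + 1L))
        cand <- setdiff(cand, c(j - 1L, j, j + 1L))
      }
      sort(firsts)
    }
    add <- function(idx, class, reason) {
      if (length(idx))
        planted[[length(planted) + 1L]] <<-
          data.frame(id = markers$id[idx], class = class, reason = reason,
                     stringsAsFactors = FALSE)
    }

    k <- n_of(spec$maf, p)
    if (k) { sel <- take(k)
      # exactly 1% B alleles, carried as heterozygotes: MAF 0.01 < 0.02
      n_b <- max(1L, round(0.01 * 2 * n))
      for (j in sel) {
        codes[, j] <- 0L
        codes[sample.int(n, min(n, n_b)), j] <- 1L
      }
      add(sel, "low_maf", "maf") }
    k <- n_of(spec$hwe, p)
    if (k) { sel <- take(k)
      for (j in sel) codes[, j] <- 2L * rbinom(n, 1L, 0.5)
      add(sel, "hwe_violation", "hwe") }
    k <- n_of(spec$marker_callrate, p)
    if (k) { sel <- take(k)
      for (j in sel) codes[sample.int(n, max(1L, round(0.04 * n))), j] <- NA
      add(sel, "low_marker_callrate", "marker_callrate") }
    k <- n_of(spec$dup_position, p) %/% 2L
    if (k) { sel <- take(k, pairs = TRUE)
      markers$pos[sel + 1L] <- markers$pos[sel]
      add(c(rbind(sel, sel + 1L)), "dup_position", "dup_position") }
    k <- n_of(spec$dup_column, p) %/% 2L
    ld_pairs <- integer(0)
    if (k) { sel <- take(k, pairs = TRUE, window_safe = TRUE)
      codes[, sel + 1L] <- codes[, sel, drop = FALSE]
      ld_pairs <- c(sel, sel + 1L)
      # identical columns tie on MAF; the later-positioned copy is pruned
      add(sel + 1L, "dup_column", "ld_prune") }
    k <- n_of(spec$gencall, p)
    if (k) { sel <- take(k)
      markers$gencall[sel] <- 0.5
      add(sel, "low_gencall", "gencall") }
    k <- n_of(spec$nonautosomal, p)
    if (k) { sel <- take(k)
      markers$chrom[sel] <- "X"
      add(sel, "nonautosomal", "nonautosomal") }

    planted_samples <- NULL
    k <- n_of(spec$sample_callrate, n)
    if (k) {
      rows <- sort(sample.int(n, k))
      # keep planted duplicate pairs bit-identical so their MAF tie (and
      # hence the documented later-marker removal) is preserved
      open_cols <- setdiff(seq_len(p), ld_pairs)
      for (i in rows)
        codes[i, sample(open_cols, round(0.15 * p))] <- NA
      planted_samples <- data.frame(id = genotypes$samples[rows],
                                    class = "low_sample_callrate",
                                    reason = "sample_callrate",
                                    stringsAsFactors = FALSE)
    }
    out <- geno_matrix(codes, markers, genotypes$samples)
    attr(out, "planted") <- do.call(
      rbind, c(planted, list(data.frame(id = character(0), class = character(0),
                                        reason = character(0)))))
    attr(out, "planted_samples") <- planted_samples
    out
  })
}

#' Simulate a complete half-sib study population
#'
#' One-call generator combining [simulate_founder_haplotypes()],
#' [simulate_pedigree()], [drop_genotypes()] and [simulate_phenotypes()],
#' returning genotypes for the phenotyped offspring. Defaults are desk-scale
#' (2000 offspring, 5000 markers on 10 chromosomes) while preserving the
#' n << p regime and the paternal half-sib family structure (about six
#' offspring per sire) of commercial beef-cattle designs.
#'
#' @param n_sires,n_dams,n_offspring Pedigree dimensions.
#' @param n_chrom,markers_per_chrom,chrom_len_cm,ld_block_len,ld_rho Passed to
#'   [simulate_founder_haplotypes()].
#' @param config A [trait_config()].
#' @param missing_rate Genotype missingness rate.
#' @param seed Integer seed driving every stage.
#' @param genotype_parents Also return founder genotypes (default `FALSE`).
#' @return List with `genotypes` ([geno_matrix()] of offspring),
#'   `pedigree`, `phenotypes`, `truth`, `panel`, and (optionally)
#'   `parent_genotypes`.
#' @export
sim_halfsib_population <- function(n_sires = 294, n_dams = 1546,
                                   n_offspring = 2000, n_chrom = 10,
                                   markers_per_chrom = 500,
                                   chrom_len_cm = 100, ld_block_len = 5,
                                   ld_rho = 0.93, config = trait_config(),
                                   missing_rate = 0, seed = NULL,
                                   genotype_parents = FALSE) {
  seeds <- if (is.null(seed)) rep(list(NULL), 4L) else as.list(seed + 0:3)
  panel <- simulate_founder_haplotypes(
    n_sires + n_dams, n_chrom = n_chrom, markers_per_chrom = markers_per_chrom,
    chrom_len_cm = chrom_len_cm, ld_block_len = ld_block_len, ld_rho = ld_rho,
    seed = seeds[[1L]])
  ped <- simulate_pedigree(n_sires, n_dams, n_offspring, seed = seeds[[2L]])
  off <- ped$id[ped$sire != "0"]
  ids <- if (genotype_parents) ped$id else off
  geno <- drop_genotypes(panel, ped, missing_rate = missing_rate,
                         seed = seeds[[3L]], animals = ids)
  geno_off <- if (genotype_parents) geno[off, ] else geno
  sim <- simulate_phenotypes(geno_off, ped, config, seed = seeds[[4L]])
  out <- list(genotypes = geno_off, pedigree = ped,
              phenotypes = sim$phenotypes, truth = sim$truth, panel = panel)
  if (genotype_parents) out$parent_genotypes <- geno[setdiff(ped$id, off), ]
  out
}
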