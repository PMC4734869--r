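# Synthetic population generator: founder LD, pedigree structure, Mendelian
# gene dropping, trait construction, and planted defects.

test_that("founder haplotype panels are polymorphic, ordered and seed-stable", {
  panel <- simulate_founder_haplotypes(60, n_chrom = 3, markers_per_chrom = 40,
                                       seed = 11)
  expect_true(all(panel$haplotypes %in% 0:1))
  cs <- colSums(panel$haplotypes)
  expect_true(all(cs > 0 & cs < nrow(panel$haplotypes)))
  by_chr <- split(panel$map$cm, panel$map$chrom)
  expect_true(all(vapply(by_chr, function(x) all(diff(x) > 0), TRUE)))
  panel2 <- simulate_founder_haplotypes(60, n_chrom = 3,
                                        markers_per_chrom = 40, seed = 11)
  expect_identical(panel, panel2)
  expect_error(simulate_founder_haplotypes(0), "n_founders")
})

test_that("block length controls adjacent LD down to the independence baseline", {
  mean_adj_r2 <- function(block_len, seed) {
    panel <- simulate_founder_haplotypes(150, n_chrom = 2,
                                         markers_per_chrom = 80,
                                         ld_block_len = block_len, seed = seed)
    g <- geno_matrix(panel$haplotypes,
                     data.frame(id = panel$map$marker, chrom = panel$map$chrom,
                                pos = panel$map$pos))
    adjacent_ld_summary(g)
  }
  with_ld <- mean(vapply(1:3, function(s) mean_adj_r2(5, s), 0))
  without <- mean(vapply(1:3, function(s) mean_adj_r2(0, s), 0))
  baseline <- 1 / (2 * 150) # E[r2] ~ 1/n for independent columns
  expect_gt(with_ld, 0.15)
  expect_lt(without, 5 * baseline)
})

test_that("half-sib pedigrees match the study design", {
  ped <- simulate_pedigree(294, 1546, 1756, seed = 5)
  off <- ped[ped$sire != "0", ]
  expect_identical(nrow(off), 1756L)
  # mean paternal family size ~ 1756 / 294 = 5.97
  expect_equal(mean(table(off$sire)), 5.97, tolerance = 0.02)
  # 1546 dams for 1756 offspring: reuse is rare
  expect_lte(max(table(off$dam)), 2)
  # dams unique when enough are available
  ped2 <- simulate_pedigree(10, 120, 100, seed = 5)
  expect_false(anyDuplicated(ped2$dam[ped2$sire != "0"]) > 0)
  ped3 <- simulate_pedigree(1, 60, 50, seed = 1)
  expect_true(all(ped3$sire[ped3$sire != "0"] == ped3$sire[ped3$sire != "0"][1]))
  expect_identical(ped, simulate_pedigree(294, 1546, 1756, seed = 5))
  expect_error(simulate_pedigree(0, 10, 10), "n_sires")
})

test_that("gene dropping is Mendelian, complete and seed-stable", {
  sim <- tiny_population()
  codes <- sim$genotypes$codes
  pcode <- sim$parent_genotypes$codes
  expect_true(all(!is.na(codes)))
  ped <- sim$pedigree
  off <- ped[ped$sire != "0", ]
  # both parents homozygous => offspring fixed at the shared homozygote
  for (k in c(1, 50, 100)) {
    trio <- off[k, ]
    s <- pcode[trio$sire, ]; d <- pcode[trio$dam, ]; o <- codes[trio$id, ]
    hom00 <- s == 0 & d == 0
    hom22 <- s == 2 & d == 2
    expect_true(all(o[hom00] == 0))
    expect_true(all(o[hom22] == 2))
    # opposite homozygotes force heterozygous offspring
    expect_true(all(o[(s == 2 & d == 0) | (s == 0 & d == 2)] == 1))
  }
  redo <- drop_genotypes(sim$panel, sim$pedigree, seed = 103,
                         animals = rownames(codes))
  # same seed reproduces (tiny_population uses seed 101 + stage offset 2)
  expect_identical(
    drop_genotypes(sim$panel, sim$pedigree, seed = 103,
                   animals = rownames(codes))$codes,
    redo$codes)
  # missing_rate inserts misses at the requested rate
  miss <- drop_genotypes(sim$panel, sim$pedigree, missing_rate = 0.1,
                         seed = 7, animals = off$id)
  expect_equal(mean(is.na(miss$codes)), 0.1, tolerance = 0.01)
  expect_error(drop_genotypes(simulate_founder_haplotypes(5, 1, 10, seed = 1),
                              sim$pedigree),
               "configuration error")
})

test_that("gene dropping conserves allele frequencies and parent-offspring G", {
  sim <- tiny_population()
  founders <- sim$pedigree$id[sim$pedigree$sire == "0"]
  f_freq <- colMeans(sim$parent_genotypes$codes) / 2
  o_freq <- colMeans(sim$genotypes$codes) / 2
  expect_lt(mean(abs(f_freq - o_freq)), 0.03)
  # VanRaden G between parents and offspring ~ 0.5
  all_codes <- rbind(sim$parent_genotypes$codes, sim$genotypes$codes)
  G <- vanraden_g(all_codes)
  off <- sim$pedigree[sim$pedigree$sire != "0", ]
  po <- G[cbind(match(off$sire, rownames(G)), match(off$id, rownames(G)))]
  expect_equal(mean(po), 0.5, tolerance = 0.05)
})

test_that("trait simulation hits the target heritability and CG structure", {
  sim <- tiny_population()
  expect_equal(sim$truth$realized_h2, 0.3, tolerance = 1e-6)
  expect_true(all(table(sim$phenotypes$cg) >= 3))
  expect_identical(nrow(sim$phenotypes), 240L)
  # high-heritability limit: phenotype minus fixed effects tracks TBV
  hi <- simulate_phenotypes(sim$genotypes, sim$pedigree,
                            trait_config(h2 = 0.999, n_qtl = 60), seed = 9)
  cg_eff <- hi$truth$cg_effects[as.integer(sub("CG", "", hi$phenotypes$cg))]
  adj <- hi$phenotypes$value - cg_eff -
    hi$truth$beta_age * (hi$phenotypes$age - 731.9)
  expect_gt(cor(adj, hi$truth$tbv), 0.99)
  # realized h2 tracks the target across replicates
  h2s <- vapply(1:5, function(s) {
    simulate_phenotypes(sim$genotypes, sim$pedigree,
                        trait_config(h2 = 0.17, n_qtl = 40),
                        seed = s)$truth$realized_h2
  }, 0)
  expect_lt(max(abs(h2s - 0.17)), 0.03)
  expect_error(simulate_phenotypes(sim$genotypes, sim$pedigree,
                                   trait_config(h2 = 1.5)), "h2")
})

test_that("planted QC defects are labelled and leave clean matrices alone", {
  sim <- tiny_population()
  g <- sim$genotypes
  expect_identical(inject_qc_defects(g, defect_spec(), seed = 1)$codes,
                   g$codes)
  spec <- defect_spec(maf = 0.02, hwe = 0.02, dup_column = 0.02,
                      dup_position = 0.02, gencall = 0.02)
  gd <- inject_qc_defects(g, spec, seed = 31)
  planted <- attr(gd, "planted")
  expect_true(nrow(planted) > 0)
  expect_true(all(planted$class %in%
    c("low_maf", "hwe_violation", "dup_column", "dup_position",
      "low_gencall")))
  # duplicated column pairs have r2 exactly 1
  dup <- planted$id[planted$class == "dup_column"]
  j <- match(dup[1], gd$markers$id)
  expect_equal(pairwise_r2(gd$codes[, j], gd$codes[, j - 1L]), 1)
  # planted low-MAF markers fall under the 0.02 threshold
  low <- planted$id[planted$class == "low_maf"]
  expect_true(all(apply(gd$codes[, low, drop = FALSE], 2, compute_maf) < 0.02))
})
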