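# Shared fixtures, built once per session and cached. Everything is
# generated in code from fixed seeds; no data files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# small half-sib population with phenotypes and parent genotypes
tiny_population <- function() {
  fixture("tiny_population", function() {
    sim_halfsib_population(
      n_sires = 40, n_dams = 240, n_offspring = 240, n_chrom = 2,
      markers_per_chrom = 120, config = trait_config(h2 = 0.3, n_qtl = 60),
      seed = 101, genotype_parents = TRUE)
  })
}

# moderate population for prediction tests (no parents, more markers)
med_population <- function() {
  fixture("med_population", function() {
    sim_halfsib_population(
      n_sires = 80, n_dams = 600, n_offspring = 600, n_chrom = 5,
      markers_per_chrom = 160, config = trait_config(h2 = 0.25, n_qtl = 120),
      seed = 202)
  })
}

# step-1 fit and pseudo-phenotypes on the moderate population
med_step1 <- function() {
  fixture("med_step1", function() {
    sim <- med_population()
    fit <- animal_model(value ~ cg + age, sim$phenotypes, sim$pedigree,
                        n_iter = 10000, burn_in = 2500, thin = 5, seed = 33)
    list(fit = fit, pseudo = pseudo_phenotypes(fit),
         W = impute_genotypes(sim$genotypes)$codes, sim = sim)
  })
}

# deterministic dosage matrix with marker metadata for QC unit tests
manual_geno <- function(codes, chrom = NULL, pos = NULL, gencall = NULL) {
  p <- ncol(codes)
  geno_matrix(codes, data.frame(
    id = sprintf("m%03d", seq_len(p)),
    chrom = if (is.null(chrom)) rep("1", p) else chrom,
    pos = if (is.null(pos)) seq_len(p) * 1000 else pos,
    gencall = if (is.null(gencall)) rep(1, p) else gencall,
    stringsAsFactors = FALSE))
}
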