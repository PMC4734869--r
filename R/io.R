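# Text IO: PLINK PED/MAP, the matrix TSV dialect, and the simulation bundle.

#' Write genotypes as PLINK PED/MAP
#'
#' Codes map to allele pairs of the marker's `allele_a`/`allele_b` letters
#' (0 -> "A A", 1 -> "A B", 2 -> "B B", missing -> "0 0"). The MAP file has
#' chromosome, marker id, genetic position (cM) and base-pair position.
#'
#' @param genotypes A [geno_matrix()].
#' @param prefix Output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(genotypes, prefix) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  codes <- genotypes$codes
  m <- genotypes$markers
  n <- nrow(codes); p <- ncol(codes)
  al <- matrix("0", n, 2L * p)
  for (j in seq_len(p)) {
    gj <- codes[, j]
    a <- m$allele_a[j]; b <- m$allele_b[j]
    a1 <- ifelse(is.na(gj), "0", ifelse(gj >= 1, b, a))
    a2 <- ifelse(is.na(gj), "0", ifelse(gj == 2, b, a))
    al[, 2L * j - 1L] <- a1
    al[, 2L * j] <- a2
  }
  ped <- data.table::data.table(fid = genotypes$samples,
                                iid = genotypes$samples,
                                pat = "0", mat = "0", sex = "0", pheno = "-9")
  ped <- cbind(ped, data.table::as.data.table(al))
  data.table::fwrite(ped, paste0(prefix, ".ped"), sep = " ",
                     col.names = FALSE, quote = FALSE)
  cm <- if (!is.null(m$cm)) m$cm else m$pos / 1e6
  map <- data.table::data.table(chrom = m$chrom, id = m$id, cm = cm,
                                pos = m$pos)
  data.table::fwrite(map, paste0(prefix, ".map"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Read genotypes from PLINK PED/MAP
#'
#' Codes count copies of the B allele, taken as the second allele observed at
#' each marker (alphabetically second on ties), so a [write_plink()] round
#' trip is exact. GenCall scores are not representable in PED/MAP and are set
#' to 1.
#'
#' @param prefix Path prefix of the `.ped` / `.map` pair.
#' @return A [geno_matrix()].
#' @export
read_plink <- function(prefix) {
  map_path <- paste0(prefix, ".map"); ped_path <- paste0(prefix, ".ped")
  if (!file.exists(map_path) || !file.exists(ped_path))
    stop_arg("missing PLINK files at prefix: ", prefix)
  map <- data.table::fread(map_path, header = FALSE,
                           colClasses = list(character = c(1L, 2L)))
  data.table::setnames(map, c("chrom", "id", "cm", "pos"))
  ped <- data.table::fread(ped_path, header = FALSE, colClasses = "character")
  samples <- ped[[2L]]
  al <- as.matrix(ped[, -(1:6)])
  p <- nrow(map)
  if (ncol(al) != 2L * p) stop_arg("PED/MAP marker counts disagree")
  codes <- matrix(NA_real_, length(samples), p)
  allele_a <- character(p); allele_b <- character(p)
  for (j in seq_len(p)) {
    a1 <- al[, 2L * j - 1L]; a2 <- al[, 2L * j]
    obs <- c(a1, a2); obs <- obs[obs != "0"]
    alleles <- sort(unique(obs))
    if (length(alleles) == 0L) alleles <- c("A", "B")
    if (length(alleles) == 1L) alleles <- c(alleles, ".")
    allele_a[j] <- alleles[1L]; allele_b[j] <- alleles[2L]
    miss <- a1 == "0" | a2 == "0"
    codes[, j] <- (a1 == alleles[2L]) + (a2 == alleles[2L])
    codes[miss, j] <- NA
  }
  markers <- data.frame(id = map$id, chrom = map$chrom, pos = map$pos,
                        cm = map$cm, allele_a = allele_a, allele_b = allele_b,
                        gencall = 1.0, stringsAsFactors = FALSE)
  geno_matrix(codes, markers, samples)
}

#' Write / read the genotype matrix TSV dialect
#'
#' Animals in rows (first column `animal`), markers as columns with a header
#' row of marker ids, missing entries written as `NA`. Marker metadata
#' (chromosome, position, GenCall score) travels in a sidecar
#' `<path>.markers.tsv`.
#'
#' @param genotypes A [geno_matrix()].
#' @param path Output TSV path.
#' @return `path` (write) or a [geno_matrix()] (read).
#' @export
write_geno_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  dt <- data.table::data.table(animal = genotypes$samples)
  dt <- cbind(dt, data.table::as.data.table(genotypes$codes))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
  data.table::fwrite(genotypes$markers, paste0(path, ".markers.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  samples <- as.character(dt[[1L]])
  codes <- as.matrix(dt[, -1L])
  side <- paste0(path, ".markers.tsv")
  markers <- if (file.exists(side)) {
    as.data.frame(data.table::fread(side, colClasses = list(
      character = c("id", "chrom"))))
  } else {
    data.frame(id = colnames(codes), chrom = "1",
               pos = seq_len(ncol(codes)), stringsAsFactors = FALSE)
  }
  geno_matrix(codes, markers, samples)
}

#' Write a simulated study bundle to disk
#'
#' Emits the generator's standard file set: PLINK `.ped`/`.map` genotypes, a
#' pedigree TSV (animal, sire, dam; 0 = unknown), a phenotype TSV (animal,
#' trait, value, cg, age, herd), and a truth TSV (animal, tbv). TSVs carry a
#' seed-stamped header comment.
#'
#' @param sim A [sim_halfsib_population()] result.
#' @param dir Output directory (created if needed).
#' @param trait Trait label written into the phenotype TSV.
#' @param seed Seed recorded in the header comments.
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(sim, dir, trait = "trait", seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# genopred simulation bundle; seed=%s", seed)
  write_plink(sim$genotypes, file.path(dir, "genotypes"))
  write_stamped <- function(df, path) {
    con <- file(path, "w")
    writeLines(stamp, con)
    close(con)
    suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
  }
  write_stamped(as.data.frame(sim$pedigree), file.path(dir, "pedigree.tsv"))
  ph <- sim$phenotypes
  ph <- data.frame(animal = ph$animal, trait = trait, value = ph$value,
                   cg = ph$cg, age = ph$age, herd = ph$herd)
  write_stamped(ph, file.path(dir, "phenotypes.tsv"))
  write_stamped(data.frame(animal = names(sim$truth$tbv),
                           tbv = unname(sim$truth$tbv)),
                file.path(dir, "truth.tsv"))
  invisible(dir)
}

read_tsv_commented <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, colClasses = "character", ...)
}

#' Read pedigree / phenotype TSVs written by [write_sim_bundle()]
#'
#' @param path File path.
#' @return A `data.frame` (pedigree: id, sire, dam; phenotypes: animal,
#'   trait, value, cg, age, herd with numeric columns converted).
#' @export
read_pedigree_tsv <- function(path) {
  ped <- read_tsv_commented(path)
  names(ped)[1:3] <- c("id", "sire", "dam")
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' @rdname read_pedigree_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  ph <- read_tsv_commented(path)
  for (nm in intersect(c("value", "age"), names(ph)))
    ph[[nm]] <- as.numeric(ph[[nm]])
  ph
}
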