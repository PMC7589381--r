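PROTO <- "TGCACGGATCTGAACGTCCA"

test_that("gene family simulation respects identity range and determinism", {
  # zero-divergence trivial case
  fam <- simulate_gene_family(2, 300, c(1, 1), seed = 1)
  expect_identical(unname(fam$sequences[[1]]), unname(fam$sequences[[2]]))

  # within-family identity lands inside the requested band
  fam <- simulate_gene_family(4, 900, c(0.89, 0.99), seed = 7)
  off <- fam$identity_matrix[upper.tri(fam$identity_matrix)]
  expect_length(off, 6L)
  expect_true(all(off >= 0.89 & off <= 0.99))

  # same seed => byte-identical; different seed differs
  fam2 <- simulate_gene_family(4, 900, c(0.89, 0.99), seed = 7)
  expect_identical(fam$sequences, fam2$sequences)
  fam3 <- simulate_gene_family(4, 900, c(0.89, 0.99), seed = 8)
  expect_false(identical(fam$sequences, fam3$sequences))
})

test_that("planted site is conserved except a single SNP at the stated position", {
  site <- planted_site(PROTO, "TGG", snp_copy = 1, snp_position_from_pam = 10)
  fam <- simulate_gene_family(4, 600, c(0.95, 0.995), site = site, seed = 21)
  s <- fam$site$start
  win <- function(x) substr(x, s, s + 22L)
  snp <- win(fam$sequences[[1]])
  others <- vapply(fam$sequences[-1], win, character(1))
  expect_true(all(others == paste0(PROTO, "TGG")))
  diffs <- which(strsplit(snp, "")[[1]] != strsplit(others[[1]], "")[[1]])
  # window base index -> protospacer position from PAM: 20,19,...,1,PAM
  expect_identical(diffs, 20L - 10L + 1L)
})

test_that("planted_site validates its invariants", {
  expect_error(planted_site("ACGT"), "20 nt")
  expect_error(planted_site(strrep("A", 20), pam = "AGT"), "NGG")
  expect_error(planted_site(strrep("A", 20), snp_copy = 1), "snp_position")
})

test_that("NHEJ alleles are distinct single-indel variants of the locus", {
  fam <- simulate_gene_family(2, 400, c(0.95, 0.99),
                              site = planted_site(PROTO, "TGG"), seed = 3)
  locus <- fam$sequences[[1]]

  expect_identical(simulate_nhej_alleles(locus, PROTO, 0), character(0))

  al <- simulate_nhej_alleles(locus, PROTO, 8, seed = 5)
  expect_length(al, 8L)
  expect_length(unique(al), 8L)
  evs <- attr(al, "events")
  for (ev in evs) expect_identical(nrow(ev), 1L) # exactly one indel each

  # single-size deletion spectrum: only one distinct allele possible
  spec6 <- indel_spectrum(insertion_probs = NULL, deletion_probs = c("-6" = 1))
  one <- simulate_nhej_alleles(locus, PROTO, 1, spectrum = spec6, seed = 2)
  expect_identical(nchar(one[[1]]), nchar(locus) - 6L)
  cl <- call_alleles(one[[1]], locus, PROTO)
  expect_identical(cl$frame_consequence, "in-frame") # two-codon loss
  expect_error(
    simulate_nhej_alleles(locus, PROTO, 2, spectrum = spec6, seed = 2),
    "too small"
  )
})

test_that("indel_spectrum validates probabilities", {
  expect_error(indel_spectrum(c("0" = 0.3)), "nonzero")
  expect_error(indel_spectrum(c("1" = 0.5), c("-1" = 0.2)), "sum to 1")
})

test_that("noiseless chromatogram base-calls reproduce the sequence", {
  seq <- "ACGTACGGTTCACGATCGATCGGATCA"
  tr <- simulate_chromatogram(seq, 1, noise_sd = 0)
  expect_identical(tr$basecalls, seq)
  expect_true(all(tr$intensities >= 0))
  expect_error(simulate_chromatogram(character(0), numeric(0)), "empty")
  expect_error(simulate_chromatogram(seq, 0.5), "sum to 1")
})

test_that("selfing pedigree follows Mendelian transmission", {
  # homozygous non-transgenic founder: all descendants identical
  founder <- plant_genotype("p0", alleles = list(A = c("A1", "A1"), B = c("Bh", "Bh")),
                            transgene_copies = 0L)
  ped <- simulate_pedigree(founder, 2, 10, seed = 4)
  for (p in ped$plants) {
    expect_identical(p$alleles$A, c("A1", "A1"))
    expect_identical(p$alleles$B, c("Bh", "Bh"))
    expect_false(any(p$transgene_copies > 0))
  }

  # hemizygous single insertion: 3:1 transgenic segregation in 400 offspring
  founder <- plant_genotype("p0", alleles = list(A = c("A1", "Ah")),
                            transgene_copies = 1L)
  ped <- simulate_pedigree(founder, 1, 400, seed = 9)
  kids <- Filter(function(p) p$generation == "T2", ped$plants)
  frac <- mean(vapply(kids, function(p) any(p$transgene_copies > 0), logical(1)))
  ci <- qbinom(c(0.025, 0.975), 400, 0.75) / 400
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])

  # germline-excluded mutations are never transmitted
  founder <- plant_genotype(
    "p0", alleles = list(E = c("E1", "E2", "E3", "E4", "Eh")),
    germline = list(E = "Eh"), transgene_copies = 1L
  )
  ped <- simulate_pedigree(founder, 2, 15, seed = 11)
  offspring <- Filter(function(p) p$plant_id != "p0", ped$plants)
  all_alleles <- unlist(lapply(offspring, function(p) p$alleles$E))
  expect_true(all(all_alleles == "Eh"))
})

test_that("pedigree genotype frequencies fit 1:2:1 at a heterozygous locus", {
  founder <- plant_genotype("p0", alleles = list(A = c("A1", "Ah")))
  ped <- simulate_pedigree(founder, 1, 1000, seed = 13)
  kids <- Filter(function(p) p$plant_id != "p0", ped$plants)
  geno <- vapply(kids, function(p) paste(sort(p$alleles$A), collapse = "/"), character(1))
  counts <- c(sum(geno == "A1/A1"), sum(geno == "A1/Ah"), sum(geno == "Ah/Ah"))
  gof <- chisq.test(counts, p = c(1, 2, 1) / 4)
  expect_gte(gof$p.value, 0.01)
})

test_that("phenotype simulation reproduces requested effects", {
  spec <- phenotype_effect_spec(
    control_means = c(pa = 10),
    effects = list(control = c(pa = 1), mutant = c(pa = 1)),
    cv = 0.05, n_replicates = 50, seed = 3
  )
  tab <- simulate_phenotypes(spec)
  m <- tapply(tab$value, tab$line, mean)
  expect_lt(abs(m[["mutant"]] - m[["control"]]) / m[["control"]], 0.05)

  # threefold effect recovered within 10%
  spec3 <- phenotype_effect_spec(
    control_means = c(pi = 1),
    effects = list(control = c(pi = 1), triple = c(pi = 3)),
    cv = 0.08, n_replicates = 20, seed = 5
  )
  tab3 <- simulate_phenotypes(spec3)
  m3 <- tapply(tab3$value, tab3$line, mean)
  expect_lt(abs(m3[["triple"]] / m3[["control"]] - 3), 0.3)

  expect_error(phenotype_effect_spec(c(pa = -1), list(control = c(pa = 1))), "positive")
  expect_error(phenotype_effect_spec(c(pa = 1), list(mutant = c(pa = 1))), "control")
  expect_error(
    phenotype_effect_spec(c(pa = 1), list(control = c(pa = 1)), cv = 1.5),
    "cv"
  )
})
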