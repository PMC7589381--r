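PROTO <- "TGCACGGATCTGAACGTCCA"

test_that("enumerate_sites finds every NGG-adjacent 20-mer on both strands", {
  s <- paste0(strrep("A", 20), "TGG")
  sites <- enumerate_sites(s)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$strand, "+")
  expect_identical(sites$protospacer, strrep("A", 20))
  expect_equal(sites$gc_percent, 0)
  expect_identical(sites$start, 0L)

  expect_identical(nrow(enumerate_sites("ACGTACG")), 0L)

  withr::with_seed(3, {
    rnd <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  })
  sites <- enumerate_sites(rnd)
  expect_identical(nrow(sites), oracle_site_count(rnd))

  # strand symmetry: same multiset of protospacers on the reverse complement
  expect_identical(sort(enumerate_sites(rnd)$protospacer),
                   sort(enumerate_sites(revcomp(rnd))$protospacer))
})

test_that("conservation scoring localises SNPs by PAM-relative position", {
  # identical copies: all profiles empty
  fam <- simulate_gene_family(3, 500, c(1, 1),
                              site = planted_site(PROTO, "TGG"), seed = 2)
  ref <- names(fam$sequences)[1]
  cands <- enumerate_sites(fam$sequences[[1]], id = ref)
  scored <- score_conservation(cands, fam)
  planted <- which(scored$protospacer == PROTO & scored$strand == "+")
  expect_length(planted, 1L)
  prof <- scored$profile[[planted]]
  for (p in prof) {
    expect_identical(p$mismatches, integer(0))
    expect_true(p$targetable)
  }

  # planted SNP at position 10 from the PAM in copy 2
  fam <- simulate_gene_family(
    3, 500, c(0.95, 0.999),
    site = planted_site(PROTO, "TGG", snp_copy = 2, snp_position_from_pam = 10),
    seed = 4
  )
  cands <- enumerate_sites(fam$sequences[[1]], id = names(fam$sequences)[1])
  scored <- score_conservation(cands, fam)
  planted <- which(scored$protospacer == PROTO & scored$strand == "+")
  prof <- scored$profile[[planted]]
  snp_member <- names(fam$sequences)[2]
  expect_identical(prof[[snp_member]]$mismatches, 10L)
  other <- setdiff(names(prof), snp_member)
  expect_identical(prof[[other]]$mismatches, integer(0))

  # ruining the PAM GG in one copy marks it non-targetable
  fam2 <- simulate_gene_family(3, 500, c(1, 1),
                               site = planted_site(PROTO, "TGG"), seed = 6)
  s <- fam2$site$start
  broken <- fam2$sequences
  substr(broken[[2]], s + 22L, s + 22L) <- "T" # GG -> GT
  fam2$sequences <- broken
  cands <- enumerate_sites(fam2$sequences[[1]], id = names(fam2$sequences)[1])
  scored <- score_conservation(cands, fam2)
  planted <- which(scored$protospacer == PROTO & scored$strand == "+")
  expect_false(scored$profile[[planted]][[names(fam2$sequences)[2]]]$targetable)
})

test_that("filter rules implement the GC, seed-region and PAM criteria", {
  mk <- function(gc, mm_list) {
    cand <- data.frame(
      reference_paralog = "r", strand = "+", start = 0L, cut_pos = 17L,
      protospacer = strrep("A", 20), pam = "AGG", gc_percent = gc,
      stringsAsFactors = FALSE
    )
    cand$profile <- list(lapply(mm_list, function(mm) {
      list(mismatches = mm, pam_diff = FALSE, targetable = TRUE)
    }))
    cand
  }
  # GC exactly at the threshold is rejected (strict inequality)
  expect_identical(nrow(filter_candidates(mk(40, list(m = integer(0))))), 0L)
  expect_identical(nrow(filter_candidates(mk(40.1, list(m = integer(0))))), 1L)
  # one SNP at position 10 tolerated; at 5 (seed region) or two SNPs rejected
  expect_identical(nrow(filter_candidates(mk(50, list(m = 10L)))), 1L)
  expect_identical(nrow(filter_candidates(mk(50, list(m = 5L)))), 0L)
  expect_identical(nrow(filter_candidates(mk(50, list(m = c(10L, 15L))))), 0L)
  # boundary moves with seed_boundary
  expect_identical(nrow(filter_candidates(mk(50, list(m = 10L)), seed_boundary = 20)), 0L)
  # PAM difference and non-targetable members are fatal
  bad <- mk(50, list(m = integer(0)))
  bad$profile[[1]]$m$pam_diff <- TRUE
  expect_identical(nrow(filter_candidates(bad)), 0L)
  nt <- mk(50, list(m = integer(0)))
  nt$profile[[1]]$m$targetable <- FALSE
  expect_identical(nrow(filter_candidates(nt)), 0L)
})

test_that("mismatch tolerance is monotone", {
  fam <- simulate_gene_family(4, 600, c(0.90, 0.99), seed = 9)
  ref <- names(fam$sequences)[1]
  scored <- score_conservation(enumerate_sites(fam$sequences[[1]], id = ref), fam)
  strict <- filter_candidates(scored, max_mismatches = 0)
  loose <- filter_candidates(scored, max_mismatches = 1)
  key <- function(d) paste(d$start, d$strand)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("off-target scan equals the brute-force Hamming oracle", {
  withr::with_seed(12, {
    genome <- c(
      chrA = paste(sample(c("A", "C", "G", "T"), 8000, replace = TRUE), collapse = ""),
      chrB = paste(sample(c("A", "C", "G", "T"), 8000, replace = TRUE), collapse = "")
    )
    # plant near-matches: 1-mm + intact PAM, and a PAM-less copy
    near <- PROTO
    substr(near, 15, 15) <- "T"
    genome["chrA"] <- paste0(substr(genome["chrA"], 1, 3000), near, "TGG",
                             substr(genome["chrA"], 3001, 8000))
    genome["chrB"] <- paste0(substr(genome["chrB"], 1, 5000), near, "TGT",
                             substr(genome["chrB"], 5001, 8000))
  })
  hits <- off_target_scan(PROTO, genome, max_mm = 2)
  oracle <- oracle_offtarget(PROTO, genome, 2)
  expect_identical(nrow(hits), nrow(oracle))
  o <- order(hits$contig, hits$start, hits$strand)
  expect_equal(hits[o, c("contig", "start", "end", "strand", "mismatches")],
               oracle[, c("contig", "start", "end", "strand", "mismatches")],
               ignore_attr = TRUE)
  # the planted 1-mm + PAM copy is among the hits; the PAM-less one is not
  expect_true(any(hits$contig == "chrA" & hits$start == 3000))
  expect_false(any(hits$contig == "chrB" & hits$start == 5000 & hits$strand == "+"))

  # excluding the on-target interval empties the hit list
  fi <- data.frame(contig = "chrA", start = 3000, end = 3023)
  rest <- off_target_scan(PROTO, genome, family_intervals = fi, max_mm = 2)
  expect_identical(nrow(rest[rest$contig == "chrA" & rest$start == 3000, ]), 0L)
})

test_that("design_guides returns the planted conserved site, ranked deterministically", {
  site <- planted_site(PROTO, "TGG", snp_copy = 3, snp_position_from_pam = 10)
  fam <- simulate_gene_family(3, 700, c(0.93, 0.99), site = site, seed = 14)
  withr::with_seed(15, {
    genome <- vapply(fam$sequences, function(s) {
      bg <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE), collapse = "")
      paste0(substr(bg, 1, 500), s, substr(bg, 501, 1500))
    }, character(1))
    names(genome) <- paste0("chr_", names(fam$sequences))
  })
  des <- design_guides(fam, genome)
  expect_gt(nrow(des), 0L)
  expect_true(PROTO %in% des$protospacer)
  expect_true(all(des$off_target_hits == 0L))
  expect_false(is.unsorted(des$total_mismatches))
  # accepted set invariant under contig renaming
  genome2 <- genome
  names(genome2) <- paste0("x", seq_along(genome2))
  des2 <- design_guides(fam, genome2)
  expect_identical(des$protospacer, des2$protospacer)

  # a genome-wide near-match off-target kills the planted candidate
  fam_id <- simulate_gene_family(3, 400, c(1, 1),
                                 site = planted_site(PROTO, "TGG"), seed = 16)
  withr::with_seed(17, {
    decoy <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  })
  near <- PROTO
  substr(near, 12, 12) <- if (substr(near, 12, 12) == "A") "C" else "A"
  genome3 <- c(chr1 = paste0(fam_id$sequences[[1]], decoy),
               chr2 = paste0(decoy, near, "AGG"))
  # restrict enumeration artificially by filtering after design
  des3 <- design_guides(fam_id, genome3,
                        family_intervals = data.frame(
                          contig = "chr1", start = 0, end = nchar(fam_id$sequences[[1]])
                        ))
  expect_false(PROTO %in% des3$protospacer)
})
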