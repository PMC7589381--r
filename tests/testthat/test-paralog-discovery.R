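test_that("pairwise identity counts matches over alignment columns", {
  expect_equal(alignment_identity("ACGTACGTAC", "ACGTACGTAC"), 1.0)
  expect_equal(alignment_identity("ACGTACGTAC", "ACGTACGTCC"), 0.9)
  m <- pairwise_identity_matrix(c(x = "ACGTACGTAC", y = "ACGTACGTCC"))
  expect_equal(unname(diag(m)), c(1, 1))
  expect_equal(m["x", "y"], 0.9)
  expect_error(pairwise_identity_matrix(c("ACGT")), "at least 2")
  expect_error(pairwise_identity_matrix(c("ACGT", "")), "empty")
})

test_that("simulated family identities agree with the generator's target range", {
  fam <- simulate_gene_family(4, 700, c(0.90, 0.98), seed = 17)
  m <- pairwise_identity_matrix(fam$sequences)
  expect_equal(m, fam$identity_matrix)
  off <- m[upper.tri(m)]
  expect_true(all(off >= 0.90 & off <= 0.98))
})

test_that("find_paralogs recovers planted copies exactly", {
  withr::with_seed(5, {
    query <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    bg <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
    contig <- paste0(substr(bg, 1, 700), query, substr(bg, 701, 2000))
  })
  hits <- find_paralogs(query, c(chr1 = contig))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 700L)
  expect_identical(hits$end, 1000L)
  expect_equal(hits$identity, 1.0)
  expect_identical(hits$strand, "+")
  expect_identical(hits$cds_sequence, query)
})

test_that("find_paralogs matches the exhaustive sliding-window oracle", {
  fam <- simulate_gene_family(4, 300, c(0.89, 0.99), seed = 23)
  withr::with_seed(6, {
    spacer <- function() paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
    contig <- paste0(spacer(), fam$sequences[[1]], spacer(), fam$sequences[[2]],
                     spacer(), fam$sequences[[3]], spacer(), fam$sequences[[4]], spacer())
  })
  genome <- c(chr1 = contig)
  hits <- find_paralogs(fam$sequences[[1]], genome, min_identity = 0.8, min_coverage = 0.8)
  expect_identical(nrow(hits), 4L)
  expect_identical(nrow(hits), oracle_sliding_hits(fam$sequences[[1]], genome, 0.8))

  # a copy diverged below the identity floor is excluded
  hits_strict <- find_paralogs(fam$sequences[[1]], genome, min_identity = 0.995)
  expect_identical(nrow(hits_strict), 1L)
})

test_that("find_paralogs is strand-symmetric", {
  fam <- simulate_gene_family(2, 300, c(0.92, 0.99), seed = 31)
  withr::with_seed(8, {
    bg <- paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE), collapse = "")
    contig <- paste0(substr(bg, 1, 400), fam$sequences[[2]], substr(bg, 401, 1200))
  })
  L <- nchar(contig)
  fwd <- find_paralogs(fam$sequences[[1]], c(chr1 = contig), 0.8, 0.8)
  rev <- find_paralogs(fam$sequences[[1]], c(chr1 = revcomp(contig)), 0.8, 0.8)
  expect_identical(nrow(fwd), nrow(rev))
  expect_identical(L - fwd$end, rev$start)
  expect_identical(L - fwd$start, rev$end)
  expect_identical(setdiff(c("+", "-"), fwd$strand), rev$strand)
})

test_that("find_paralogs validates inputs", {
  expect_error(find_paralogs("ACGT", c(chr1 = strrep("A", 100))), "60 nt")
  expect_error(find_paralogs(strrep("ACGT", 20), character(0)), "empty genome")
})

test_that("single-linkage family grouping splits at the identity threshold", {
  f1 <- simulate_gene_family(3, 400, c(0.94, 0.99), seed = 41, name = "F1")
  f2 <- simulate_gene_family(3, 400, c(0.94, 0.99), seed = 42, name = "F2")
  seqs <- c(f1$sequences, f2$sequences)
  fams <- group_families(seqs, within_threshold = 0.85)
  expect_length(fams, 2L)
  members <- lapply(fams, function(f) sort(names(f$sequences)))
  expect_true(list(sort(names(f1$sequences))) %in% members ||
                identical(members[[1]], sort(names(f1$sequences))) ||
                identical(members[[2]], sort(names(f1$sequences))))

  expect_length(group_families(seqs, within_threshold = 0), 1L)
  fams_strict <- group_families(seqs, within_threshold = 1.0)
  expect_length(fams_strict, length(seqs))
})

test_that("neighbor-joining recovers 3-taxon branch lengths in closed form", {
  # three-point formulas: x = (dab + dac - dbc)/2 etc.
  d <- matrix(c(0, 0.30, 0.44, 0.30, 0, 0.50, 0.44, 0.50, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nwk <- build_distance_tree(1 - d)
  tree <- attr(nwk, "tree")
  dd <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
  expect_equal(dd, d, tolerance = 1e-10)
  expect_true(all(c("a", "b", "c") %in% tree$tip.label))
})

test_that("neighbor-joining recovers an additive 4-taxon tree", {
  d <- additive_4taxa()
  nwk <- build_distance_tree(1 - d)
  tree <- attr(nwk, "tree")
  # path distances reproduce the additive input
  dd <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
  expect_equal(dd, d, tolerance = 1e-10)
  # the a|b vs c|d split is present
  unrooted <- ape::unroot(tree)
  ab_mrca_depth <- ape::dist.nodes(unrooted)
  pair_dist <- dd["a", "b"] + dd["c", "d"]
  cross <- dd["a", "c"] + dd["b", "d"]
  expect_lt(pair_dist, cross) # four-point condition places ab together
})

test_that("distance tree separates simulated families", {
  f1 <- simulate_gene_family(3, 400, c(0.94, 0.99), seed = 51, name = "X1")
  f2 <- simulate_gene_family(3, 400, c(0.94, 0.99), seed = 52, name = "X2")
  m <- pairwise_identity_matrix(c(f1$sequences, f2$sequences))
  nwk <- build_distance_tree(m)
  tree <- attr(nwk, "tree")
  # monophyly of family 1 in the unrooted tree: the split exists
  bp <- ape::prop.part(tree)
  labs <- tree$tip.label
  f1_set <- sort(match(names(f1$sequences), labs))
  splits <- lapply(bp, sort)
  complement <- sort(setdiff(seq_along(labs), f1_set))
  expect_true(any(vapply(splits, identical, logical(1), f1_set)) ||
                any(vapply(splits, identical, logical(1), complement)))
  expect_error(build_distance_tree(matrix(c(1, 0.5, 0.2, 1), 2)), "3 taxa")
  m_bad <- m
  m_bad[1, 2] <- m_bad[1, 2] + 0.1
  expect_error(build_distance_tree(m_bad), "symmetric")
})
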