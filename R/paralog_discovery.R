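#' Pairwise identity matrix for a set of sequences
#'
#' Identity is computed from a global alignment of each pair of coding
#' sequences: matching columns divided by total alignment columns, gap
#' columns counting as mismatches. The diagonal is 1.
#'
#' @param seqs Named character vector of DNA sequences (>= 2).
#' @return Symmetric numeric matrix of identities in \[0, 1\] with dimnames.
#' @export
pairwise_identity_matrix <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (any(nchar(seqs) == 0L)) stop("empty sequence")
  n <- length(seqs)
  labels <- if (is.null(names(seqs))) paste0("seq", seq_len(n)) else names(seqs)
  m <- diag(1, n)
  dimnames(m) <- list(labels, labels)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- alignment_identity(seqs[[i]], seqs[[j]])
    }
  }
  m
}

# k-mer seed positions of query k-mers in a subject string.
# Returns data.frame(qpos, spos) of exact k-mer matches.
.kmer_seeds <- function(query, subject, k) {
  nq <- nchar(query)
  qk <- substring(query, 1:(nq - k + 1L), k:nq)
  qpos_by_kmer <- split(seq_along(qk), qk)
  ns <- nchar(subject)
  if (ns < k) return(data.frame(qpos = integer(0), spos = integer(0)))
  sk <- substring(subject, 1:(ns - k + 1L), k:ns)
  hit <- which(sk %in% names(qpos_by_kmer))
  if (!length(hit)) return(data.frame(qpos = integer(0), spos = integer(0)))
  qp <- qpos_by_kmer[sk[hit]]
  data.frame(
    qpos = unlist(qp, use.names = FALSE),
    spos = rep(hit, lengths(qp))
  )
}

# Candidate subject windows from seed diagonals. Band-clusters seeds by
# diagonal (spos - qpos), one window per cluster.
.seed_windows <- function(seeds, qlen, slen, band = 25L) {
  if (!nrow(seeds)) return(data.frame(start = integer(0), end = integer(0)))
  diag <- seeds$spos - seeds$qpos
  o <- order(diag)
  diag <- diag[o]
  grp <- cumsum(c(1L, diff(diag) > band))
  starts <- tapply(diag, grp, min)
  out <- data.frame(
    start = pmax(1L, as.integer(starts) + 1L - band),
    end = pmin(slen, as.integer(tapply(diag, grp, max)) + qlen + band)
  )
  unique(out)
}

# Align query to one subject window; returns hit coordinates on the subject
# (1-based inclusive) plus identity, coverage and score, or NULL.
.refine_hit <- function(query, subject, win_start, win_end) {
  region <- substr(subject, win_start, win_end)
  aln <- Biostrings::pairwiseAlignment(query, region,
    type = "global-local",
    substitutionMatrix = .sub_matrix(),
    gapOpening = 5, gapExtension = 2
  )
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  identity <- Biostrings::nmatch(aln) / cols
  rng <- Biostrings::subject(aln)
  s <- win_start + Biostrings::start(rng) - 1L
  e <- win_start + Biostrings::end(rng) - 1L
  coverage <- (e - s + 1L) / nchar(query)
  list(start = s, end = e, identity = identity,
       coverage = min(coverage, 1), score = Biostrings::score(aln))
}

#' Find paralogous copies of a query gene in genome contigs
#'
#' k-mer--seeded search (default k = 11) over both strands followed by
#' banded global--local alignment refinement. Non-overlapping hits with
#' identity >= `min_identity` over >= `min_coverage` of the query are
#' reported sorted by alignment score. This is the desk-scale counterpart
#' of a BLAST search for paralogs in a polyploid genome.
#'
#' @param query_cds Query coding sequence (>= 60 nt).
#' @param genome_contigs Named character vector of contig sequences.
#' @param min_identity Minimum alignment identity (fraction).
#' @param min_coverage Minimum query coverage (fraction).
#' @param k Seed k-mer length.
#' @return data.frame of paralog records: id, contig, start, end (0-based
#'   half-open), strand, identity, coverage, score, cds_sequence.
#' @export
find_paralogs <- function(query_cds, genome_contigs,
                          min_identity = 0.8, min_coverage = 0.8, k = 11L) {
  if (length(genome_contigs) == 0L) stop("empty genome")
  if (nchar(query_cds) < 60L) stop("query must be at least 60 nt")
  if (k > nchar(query_cds)) stop("k-mer longer than query")
  if (is.null(names(genome_contigs))) {
    names(genome_contigs) <- paste0("contig", seq_along(genome_contigs))
  }
  qlen <- nchar(query_cds)
  hits <- list()
  for (cn in names(genome_contigs)) {
    contig <- genome_contigs[[cn]]
    slen <- nchar(contig)
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") contig else revcomp(contig)
      wins <- .seed_windows(.kmer_seeds(query_cds, subj, k), qlen, slen)
      for (w in seq_len(nrow(wins))) {
        h <- .refine_hit(query_cds, subj, wins$start[w], wins$end[w])
        if (h$identity >= min_identity && h$coverage >= min_coverage) {
          # map minus-strand coordinates back to the forward strand
          if (strand == "-") {
            s <- slen - h$end + 1L; e <- slen - h$start + 1L
          } else {
            s <- h$start; e <- h$end
          }
          hits[[length(hits) + 1L]] <- data.frame(
            contig = cn, start = s - 1L, end = e, strand = strand,
            identity = h$identity, coverage = h$coverage, score = h$score,
            cds_sequence = if (strand == "+") substr(contig, s, e) else revcomp(substr(contig, s, e)),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(
      id = character(0), contig = character(0), start = integer(0),
      end = integer(0), strand = character(0), identity = numeric(0),
      coverage = numeric(0), score = numeric(0), cds_sequence = character(0),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, hits)
  out <- out[order(-out$score), , drop = FALSE]
  # greedy removal of hits overlapping a better one on the same contig
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      for (j in (i + 1L):nrow(out)) {
        if (keep[j] && out$contig[j] == out$contig[i] &&
            out$start[j] < out$end[i] && out$start[i] < out$end[j]) {
          keep[j] <- FALSE
        }
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out$id <- paste0("hit", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("id", "contig", "start", "end", "strand", "identity",
          "coverage", "score", "cds_sequence")]
}

#' Group paralog records into gene families by single-linkage clustering
#'
#' Members joined by any pairwise identity >= `within_threshold` fall into
#' the same family.
#'
#' @param seqs Named character vector of member CDS sequences.
#' @param within_threshold Identity threshold (default 0.85).
#' @return List of `gene_family` objects (name, sequences, identity_matrix).
#' @export
group_families <- function(seqs, within_threshold = 0.85) {
  if (length(seqs) < 1L) stop("need at least one record")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (length(seqs) == 1L) {
    fam <- structure(
      list(name = "family1", sequences = seqs,
           identity_matrix = matrix(1, 1, 1, dimnames = list(names(seqs), names(seqs))),
           site = NULL, ancestor = NULL),
      class = "gene_family"
    )
    return(list(fam))
  }
  idm <- pairwise_identity_matrix(seqs)
  hc <- stats::hclust(stats::as.dist(1 - idm), method = "single")
  cl <- stats::cutree(hc, h = 1 - within_threshold)
  lapply(sort(unique(cl)), function(g) {
    members <- names(cl)[cl == g]
    structure(
      list(
        name = paste0("family", g),
        sequences = seqs[members],
        identity_matrix = idm[members, members, drop = FALSE],
        site = NULL, ancestor = NULL
      ),
      class = "gene_family"
    )
  })
}

#' Neighbor-joining tree from an identity matrix
#'
#' Distances are 1 - identity; negative branch lengths produced by NJ are
#' clamped to zero. Returns a Newick string containing every label.
#'
#' @param identity_matrix Symmetric identity matrix with dimnames (>= 3 taxa).
#' @param labels Optional taxon labels overriding the dimnames.
#' @return Newick string (also invisibly an `ape::phylo` via attribute `tree`).
#' @export
build_distance_tree <- function(identity_matrix, labels = NULL) {
  m <- as.matrix(identity_matrix)
  if (nrow(m) < 3L) stop("need at least 3 taxa")
  if (max(abs(m - t(m))) > 1e-8) stop("identity matrix must be symmetric")
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  if (is.null(rownames(m))) {
    dimnames(m) <- list(paste0("t", seq_len(nrow(m))), paste0("t", seq_len(nrow(m))))
  }
  tree <- ape::nj(stats::as.dist(1 - m))
  tree$edge.length[tree$edge.length < 0] <- 0
  nwk <- ape::write.tree(tree)
  attr(nwk, "tree") <- tree
  nwk
}
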