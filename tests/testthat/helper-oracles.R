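# Independent brute-force oracles used to validate the package's search and
# statistics code. These deliberately avoid the implementation paths they
# check (no k-mer seeding, no Biostrings matching, no stats::aov).

# All-positions Hamming scan for near-matches of a 23-nt site
# (protospacer + NGG) on both strands. Returns forward-strand 0-based
# half-open windows.
oracle_offtarget <- function(proto, contigs, max_mm) {
  pb <- strsplit(proto, "")[[1]]
  out <- list()
  for (cn in names(contigs)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") contigs[[cn]] else crisprpoly::revcomp(contigs[[cn]])
      sb <- strsplit(s, "")[[1]]
      L <- length(sb)
      if (L < 23L) next
      npos <- L - 22L
      mm <- integer(npos)
      for (k in 1:20) mm <- mm + (sb[k:(npos + k - 1L)] != pb[k])
      pam_ok <- sb[22:(npos + 21L)] == "G" & sb[23:(npos + 22L)] == "G"
      for (i in which(mm <= max_mm & pam_ok)) {
        if (strand == "+") {
          st <- i - 1L; en <- i + 22L
        } else {
          st <- L - (i + 22L); en <- L - i + 1L
        }
        out[[length(out) + 1L]] <- data.frame(
          contig = cn, start = st, end = en, strand = strand,
          mismatches = mm[i], stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$start, res$strand), ]
}

# Exhaustive sliding-window Hamming identity scan for full-length copies of
# a query (no indels) on both strands; overlapping windows collapsed to the
# local best. Returns the count of distinct placements at or above the
# identity threshold.
oracle_sliding_hits <- function(query, contigs, min_identity) {
  qb <- strsplit(query, "")[[1]]
  q <- length(qb)
  n_hits <- 0L
  for (cn in names(contigs)) {
    best <- numeric(0)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") contigs[[cn]] else crisprpoly::revcomp(contigs[[cn]])
      sb <- strsplit(s, "")[[1]]
      L <- length(sb)
      if (L < q) next
      npos <- L - q + 1L
      match_count <- integer(npos)
      for (k in seq_len(q)) {
        match_count <- match_count + (sb[k:(npos + k - 1L)] == qb[k])
      }
      ident <- match_count / q
      # map minus-strand window starts to forward coordinates
      starts <- if (strand == "+") seq_len(npos) else L - (seq_len(npos) + q - 1L) + 1L
      ok <- ident >= min_identity
      best <- c(best, stats::setNames(ident[ok], starts[ok]))
    }
    if (!length(best)) next
    # collapse window positions within one query length of each other
    pos <- sort(as.integer(names(best)))
    n_hits <- n_hits + sum(diff(c(-q * 2L, pos)) >= q) # distinct placements
  }
  n_hits
}

# Regex-style scan counting 20-mers next to NGG on both strands.
oracle_site_count <- function(sequence) {
  count_fwd <- function(s) {
    g <- gregexpr("(?=[ACGT]{21}GG)", s, perl = TRUE)[[1]]
    sum(g > 0)
  }
  count_fwd(sequence) + count_fwd(crisprpoly::revcomp(sequence))
}

# Closed-form chi-square (df = 1) survival function via the error function:
# P(X > x) = erfc(sqrt(x / 2)).
oracle_chisq_p_df1 <- function(x) {
  2 * stats::pnorm(-sqrt(x))
}

# From-scratch one-way ANOVA via sums of squares.
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- length(means) - 1L
  df2 <- length(values) - length(means)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df1 = df1, df2 = df2, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Exhaustive gamete enumeration for n unlinked hemizygous insertions:
# fraction of selfed offspring carrying at least one insertion.
oracle_transgenic_fraction <- function(n) {
  if (n == 0L) return(0)
  combos <- expand.grid(rep(list(0:1), 2L * n))
  carrying <- apply(combos, 1, function(g) {
    any(vapply(seq_len(n), function(i) g[i] + g[n + i] > 0, logical(1)))
  })
  mean(carrying)
}

# A fixed additive 4-taxon distance matrix: topology ((a,b),(c,d)) with
# external branches 0.05/0.07/0.04/0.06 and internal branch 0.10.
additive_4taxa <- function() {
  ext <- c(a = 0.05, b = 0.07, c = 0.04, d = 0.06)
  int <- 0.10
  m <- matrix(0, 4, 4, dimnames = list(names(ext), names(ext)))
  for (i in names(ext)) {
    for (j in names(ext)) {
      if (i == j) next
      same_side <- (i %in% c("a", "b")) == (j %in% c("a", "b"))
      m[i, j] <- ext[i] + ext[j] + if (same_side) 0 else int
    }
  }
  m
}
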