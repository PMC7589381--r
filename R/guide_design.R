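#' Enumerate candidate Cas9 target sites in a sequence
#'
#' Every 20-mer immediately 5' of an NGG PAM, on either strand, is a
#' candidate. Coordinates are reported on the forward strand of the input:
#' `start` is the 0-based start of the full 23-nt site window
#' (protospacer+PAM for `+` sites, PAM+protospacer for `-` sites), and
#' `cut_pos` the 1-based forward coordinate of the base immediately 5' of
#' the blunt cut (3 bp from the PAM on the protospacer strand).
#'
#' @param sequence DNA string (>= 23 nt; shorter input yields no sites).
#' @param id Label recorded as the reference paralog.
#' @return data.frame: reference_paralog, strand, start, cut_pos,
#'   protospacer, pam, gc_percent.
#' @export
enumerate_sites <- function(sequence, id = "seq") {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  rows <- list()
  if (L >= 23L) {
    # forward strand: GG at positions g, g+1 with protospacer ending at g-2
    gg <- gregexpr("(?=GG)", sequence, perl = TRUE)[[1]]
    gg <- gg[gg > 0]
    for (g in gg) {
      w <- g - 21L # 1-based window start (protospacer start)
      if (w < 1L || g + 1L > L) next
      proto <- substr(sequence, w, w + 19L)
      rows[[length(rows) + 1L]] <- data.frame(
        reference_paralog = id, strand = "+", start = w - 1L,
        cut_pos = w + 16L,
        protospacer = proto, pam = substr(sequence, w + 20L, w + 22L),
        gc_percent = gc_percent(proto), stringsAsFactors = FALSE
      )
    }
    # minus strand: NGG on the reverse complement appears as CCN forward
    cc <- gregexpr("(?=CC)", sequence, perl = TRUE)[[1]]
    cc <- cc[cc > 0]
    for (j in cc) {
      if (j + 22L > L) next
      proto <- revcomp(substr(sequence, j + 3L, j + 22L))
      rows[[length(rows) + 1L]] <- data.frame(
        reference_paralog = id, strand = "-", start = j - 1L,
        cut_pos = j + 5L,
        protospacer = proto, pam = revcomp(substr(sequence, j, j + 2L)),
        gc_percent = gc_percent(proto), stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(
      reference_paralog = character(0), strand = character(0),
      start = integer(0), cut_pos = integer(0), protospacer = character(0),
      pam = character(0), gc_percent = numeric(0), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Position map ref -> member through a global alignment; NA where the member
# has a gap at the ref position.
.position_map <- function(ref_seq, mem_seq) {
  aln <- .align_global(ref_seq, mem_seq)
  s <- strsplit(.aligned_strings(aln), "", fixed = TRUE)
  pa <- s[[1]]; sa <- s[[2]]
  map <- integer(nchar(ref_seq)); map[] <- NA_integer_
  rpos <- 0L; mpos <- 0L
  for (i in seq_along(pa)) {
    if (sa[i] != "-") mpos <- mpos + 1L
    if (pa[i] != "-") {
      rpos <- rpos + 1L
      map[rpos] <- if (sa[i] == "-") NA_integer_ else mpos
    }
  }
  map
}

#' Score cross-paralog conservation of candidate target sites
#'
#' For each family member other than the reference, the homologous 23-nt
#' window is located through a pairwise global alignment and every differing
#' protospacer or PAM position is recorded. Mismatch positions are counted
#' from the PAM (1 = PAM-proximal, 20 = PAM-distal). A member whose
#' homologous window is disrupted by alignment gaps, or whose PAM is no
#' longer NGG, is recorded as non-targetable.
#'
#' @param candidates data.frame from [enumerate_sites()] run on the
#'   reference member of `family`.
#' @param family A `gene_family`; the reference member is named by each
#'   candidate's `reference_paralog` and must be a family member.
#' @return The candidates with a list-column `profile`: per other member a
#'   list(mismatches = integer positions from PAM, pam_diff = logical,
#'   targetable = logical).
#' @export
score_conservation <- function(candidates, family) {
  stopifnot(inherits(family, "gene_family"))
  if (!nrow(candidates)) {
    candidates$profile <- list()
    return(candidates)
  }
  refs <- unique(candidates$reference_paralog)
  if (!all(refs %in% names(family$sequences))) {
    stop("candidate reference paralog not found in the family")
  }
  members <- names(family$sequences)
  maps <- list()
  for (r in refs) {
    maps[[r]] <- lapply(
      stats::setNames(setdiff(members, r), setdiff(members, r)),
      function(m) .position_map(family$sequences[[r]], family$sequences[[m]])
    )
  }
  profiles <- vector("list", nrow(candidates))
  for (ci in seq_len(nrow(candidates))) {
    cand <- candidates[ci, ]
    ref <- cand$reference_paralog
    ref_seq <- family$sequences[[ref]]
    w <- cand$start + 1L # 1-based window start
    win <- w:(w + 22L)
    if (max(win) > nchar(ref_seq)) stop("candidate does not locate on its reference paralog")
    # forward-position -> protospacer position from PAM (NA for PAM bases)
    if (cand$strand == "+") {
      from_pam <- c(20:1, NA, NA, NA) # window base 1..20 protospacer, 21..23 PAM
      pam_idx <- 21:23
    } else {
      from_pam <- c(NA, NA, NA, 1:20) # window base 1..3 PAM, 4..23 protospacer
      pam_idx <- 1:3
    }
    prof <- list()
    for (m in setdiff(members, ref)) {
      mem_seq <- family$sequences[[m]]
      mpos <- maps[[ref]][[m]][win]
      if (anyNA(mpos) || any(diff(mpos) != 1L)) {
        prof[[m]] <- list(mismatches = integer(0), pam_diff = NA, targetable = FALSE)
        next
      }
      ref_b <- strsplit(substr(ref_seq, min(win), max(win)), "")[[1]]
      mem_b <- strsplit(substr(mem_seq, min(mpos), max(mpos)), "")[[1]]
      diff_idx <- which(ref_b != mem_b)
      mm <- sort(from_pam[setdiff(diff_idx, pam_idx)])
      pam_diff <- any(diff_idx %in% pam_idx)
      # the member's PAM must itself still read NGG in site orientation
      mem_pam <- mem_b[pam_idx]
      pam_ok <- if (cand$strand == "+") {
        all(mem_pam[2:3] == "G")
      } else {
        all(mem_pam[1:2] == "C")
      }
      prof[[m]] <- list(mismatches = mm, pam_diff = pam_diff, targetable = pam_ok)
    }
    profiles[[ci]] <- prof
  }
  candidates$profile <- profiles
  candidates
}

#' Filter scored candidates with polyploid knockout design rules
#'
#' A candidate is kept iff its GC content is strictly above `gc_min`, every
#' family member is targetable (homologous window intact and PAM identical),
#' and every member's mismatch profile has at most `max_mismatches`
#' mismatches, all lying PAM-distal of the seed region (position >=
#' `seed_boundary` counted from the PAM, boundary inclusive).
#'
#' @param candidates Scored candidates from [score_conservation()].
#' @param gc_min GC threshold in percent (strict inequality).
#' @param max_mismatches Maximum tolerated mismatches per member.
#' @param seed_boundary First protospacer position (from the PAM) at which a
#'   mismatch is tolerated.
#' @return The accepted subset, with helper columns `total_mismatches` and
#'   `n_nontargetable`.
#' @export
filter_candidates <- function(candidates, gc_min = 40, max_mismatches = 1L,
                              seed_boundary = 10L) {
  if (!nrow(candidates)) return(candidates)
  if (is.null(candidates$profile)) stop("candidates must be scored first")
  ok <- logical(nrow(candidates))
  total_mm <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    prof <- candidates$profile[[i]]
    pass <- candidates$gc_percent[i] > gc_min
    tmm <- 0L
    for (p in prof) {
      if (!isTRUE(p$targetable) || isTRUE(p$pam_diff)) { pass <- FALSE; break }
      if (length(p$mismatches) > max_mismatches) { pass <- FALSE; break }
      if (length(p$mismatches) && any(p$mismatches < seed_boundary)) { pass <- FALSE; break }
      tmm <- tmm + length(p$mismatches)
    }
    ok[i] <- pass
    total_mm[i] <- tmm
  }
  out <- candidates[ok, , drop = FALSE]
  out$total_mismatches <- total_mm[ok]
  rownames(out) <- NULL
  out
}

#' Genome-wide off-target scan for one candidate
#'
#' Scans both strands of every contig for 23-mers whose protospacer part
#' matches the candidate with at most `max_mm` mismatches and whose PAM is
#' NGG (the N is free, the GG is required). Hits overlapping the family's
#' own loci are excluded. The candidate passes iff no hit remains.
#'
#' @param candidate One-row data.frame with a `protospacer` column (or a
#'   plain 20-nt string).
#' @param genome_contigs Named character vector of contigs.
#' @param family_intervals data.frame(contig, start, end), 0-based half-open
#'   on-target loci to exclude; NULL excludes nothing.
#' @param max_mm Maximum protospacer mismatches (default 2).
#' @return data.frame of off-target hits (contig, start, end, strand,
#'   mismatches); zero rows means the candidate passes.
#' @export
off_target_scan <- function(candidate, genome_contigs, family_intervals = NULL,
                            max_mm = 2L) {
  if (length(genome_contigs) == 0L) stop("empty genome")
  proto <- if (is.character(candidate)) candidate else candidate$protospacer
  proto <- toupper(proto)
  if (is.null(names(genome_contigs))) {
    names(genome_contigs) <- paste0("contig", seq_along(genome_contigs))
  }
  hits <- list()
  pat <- Biostrings::DNAString(proto)
  for (cn in names(genome_contigs)) {
    contig <- genome_contigs[[cn]]
    L <- nchar(contig)
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") contig else revcomp(contig)
      m <- Biostrings::matchPattern(pat, Biostrings::DNAString(subj),
                                    max.mismatch = max_mm, with.indels = FALSE)
      for (s in Biostrings::start(m)) {
        if (s + 22L > L) next
        pam <- substr(subj, s + 20L, s + 22L)
        if (substr(pam, 2, 3) != "GG") next
        mm <- sum(strsplit(substr(subj, s, s + 19L), "")[[1]] !=
                    strsplit(proto, "")[[1]])
        # 0-based half-open window on the forward strand
        if (strand == "+") {
          st <- s - 1L; en <- s + 22L
        } else {
          st <- L - (s + 22L); en <- L - s + 1L
        }
        hits[[length(hits) + 1L]] <- data.frame(
          contig = cn, start = st, end = en, strand = strand,
          mismatches = mm, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else data.frame(
    contig = character(0), start = integer(0), end = integer(0),
    strand = character(0), mismatches = integer(0), stringsAsFactors = FALSE
  )
  if (!is.null(family_intervals) && nrow(out)) {
    keep <- vapply(seq_len(nrow(out)), function(i) {
      fi <- family_intervals[family_intervals$contig == out$contig[i], , drop = FALSE]
      !any(out$start[i] < fi$end & fi$start < out$end[i])
    }, logical(1))
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Design conserved guides for a paralog family
#'
#' Composes [enumerate_sites()] on the reference member,
#' [score_conservation()], [filter_candidates()] and [off_target_scan()].
#' Accepted guides are ranked by fewest total cross-paralog mismatches, then
#' highest GC content, then 5'-most position; the ranking is deterministic.
#'
#' @param family A `gene_family`.
#' @param genome_contigs Named character vector; the genome screened for
#'   off-targets.
#' @param family_intervals 0-based half-open on-target loci to exclude from
#'   the off-target scan. If NULL, the family members are located in the
#'   genome by exact match (both strands).
#' @param reference Family member on which sites are enumerated (default:
#'   first member).
#' @param gc_min,max_mismatches,seed_boundary See [filter_candidates()].
#' @param offtarget_mm See [off_target_scan()].
#' @return Ranked accepted candidates with an `off_target_hits` column.
#'   Attribute `diagnostics` records how many candidates each stage removed.
#' @export
design_guides <- function(family, genome_contigs, family_intervals = NULL,
                          reference = NULL, gc_min = 40, max_mismatches = 1L,
                          seed_boundary = 10L, offtarget_mm = 2L) {
  stopifnot(inherits(family, "gene_family"))
  if (is.null(reference)) reference <- names(family$sequences)[1]
  if (is.null(family_intervals)) {
    family_intervals <- locate_family_intervals(family, genome_contigs)
  }
  cands <- enumerate_sites(family$sequences[[reference]], id = reference)
  scored <- score_conservation(cands, family)
  filtered <- filter_candidates(scored, gc_min, max_mismatches, seed_boundary)
  n_ot_fail <- 0L
  if (nrow(filtered)) {
    ot <- integer(nrow(filtered))
    for (i in seq_len(nrow(filtered))) {
      ot[i] <- nrow(off_target_scan(filtered[i, ], genome_contigs,
                                    family_intervals, max_mm = offtarget_mm))
    }
    filtered$off_target_hits <- ot
    n_ot_fail <- sum(ot > 0L)
    filtered <- filtered[ot == 0L, , drop = FALSE]
  } else {
    filtered$off_target_hits <- integer(0)
  }
  o <- order(filtered$total_mismatches, -filtered$gc_percent, filtered$start)
  out <- filtered[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "diagnostics") <- list(
    enumerated = nrow(cands),
    after_filter = nrow(filtered) + n_ot_fail,
    off_target_rejected = n_ot_fail,
    accepted = nrow(out)
  )
  if (!nrow(out)) {
    message("design_guides: no candidate survived filtering/off-target screening for ",
            family$name)
  }
  out
}

#' Locate family member sequences in genome contigs by exact match
#'
#' @param family A `gene_family`.
#' @param genome_contigs Named character vector.
#' @return data.frame(member, contig, start, end, strand), 0-based half-open.
#' @export
locate_family_intervals <- function(family, genome_contigs) {
  if (is.null(names(genome_contigs))) {
    names(genome_contigs) <- paste0("contig", seq_along(genome_contigs))
  }
  rows <- list()
  for (m in names(family$sequences)) {
    seq <- family$sequences[[m]]
    found <- FALSE
    for (cn in names(genome_contigs)) {
      hit <- regexpr(seq, genome_contigs[[cn]], fixed = TRUE)
      if (hit > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          member = m, contig = cn, start = as.integer(hit) - 1L,
          end = as.integer(hit) - 1L + nchar(seq), strand = "+",
          stringsAsFactors = FALSE
        )
        found <- TRUE
        break
      }
      hit <- regexpr(revcomp(seq), genome_contigs[[cn]], fixed = TRUE)
      if (hit > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          member = m, contig = cn, start = as.integer(hit) - 1L,
          end = as.integer(hit) - 1L + nchar(seq), strand = "-",
          stringsAsFactors = FALSE
        )
        found <- TRUE
        break
      }
    }
    if (!found) stop("family member ", m, " not found in the genome; pass family_intervals")
  }
  do.call(rbind, rows)
}
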