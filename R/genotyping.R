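# --- indel event machinery -------------------------------------------------
#
# An event table has columns kind ("insertion"/"deletion"), position
# (cut-relative: for deletions the first deleted reference base, position 1
# being the base immediately 3' of the cut; for insertions the reference
# base after which the insertion sits, 0 meaning "at the cut"), length and
# sequence (inserted bases; empty for deletions). Events are left-normalised
# (VCF-style leftmost placement) so that allele identity is well defined.

.empty_events <- function() {
  data.frame(
    kind = character(0), position = integer(0), length = integer(0),
    sequence = character(0), stringsAsFactors = FALSE
  )
}

# Left-normalise cut-relative events against the reference string.
.normalize_events <- function(events, reference, cut_pos) {
  if (!nrow(events)) return(events)
  ref_b <- strsplit(reference, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(events))) {
    if (events$kind[i] == "deletion") {
      a <- cut_pos + events$position[i] # absolute first deleted base
      k <- events$length[i]
      while (a > 1L && ref_b[a - 1L] == ref_b[a + k - 1L]) a <- a - 1L
      events$position[i] <- a - cut_pos
    } else {
      p <- cut_pos + events$position[i] # insertion after absolute position p
      s <- strsplit(events$sequence[i], "", fixed = TRUE)[[1]]
      k <- length(s)
      while (p >= 1L && ref_b[p] == s[k]) {
        s <- c(ref_b[p], s[-k])
        p <- p - 1L
      }
      events$position[i] <- p - cut_pos
      events$sequence[i] <- paste(s, collapse = "")
    }
  }
  events <- events[order(events$position, events$kind), , drop = FALSE]
  rownames(events) <- NULL
  events
}

.event_signature <- function(events) {
  if (!nrow(events)) return("WT")
  paste(
    vapply(seq_len(nrow(events)), function(i) {
      paste(events$kind[i], events$position[i], events$length[i],
            events$sequence[i], sep = ":")
    }, character(1)),
    collapse = ";"
  )
}

#' Call mutant allele events from a read against a wild-type reference
#'
#' Globally aligns the read to the reference with affine gap penalties,
#' extracts insertion/deletion events, left-normalises them and reports
#' their positions relative to the Cas9 cut site. Substitutions are treated
#' as sequencing noise: reads with more than `max_noise_subs` substitutions
#' outside a +/- `window` nt window around the cut, or with alignment
#' identity below `min_identity`, are rejected as foreign amplicons.
#'
#' @param read_seq The amplicon or plasmid-clone sequence.
#' @param reference_seq Wild-type reference sequence.
#' @param guide 20-nt protospacer present in the reference next to an NGG
#'   PAM, or an integer cut position (1-based forward coordinate of the base
#'   immediately 5' of the cut).
#' @param window Half-width in nt of the cut window inside which
#'   substitutions are not counted against the noise limit.
#' @param max_noise_subs Maximum substitutions tolerated outside the window.
#' @param min_identity Alignment identity floor below which the read is
#'   rejected.
#' @param coding Is the locus coding and in frame at the cut? Controls
#'   whether a frame consequence is computed.
#' @return An `allele_call`: list with `events` (normalised event table),
#'   `wild_type`, `frame_consequence` ("none", "in-frame" or "frameshift"),
#'   and `n_noise_substitutions`.
#' @export
call_alleles <- function(read_seq, reference_seq, guide,
                         window = 30L, max_noise_subs = 2L,
                         min_identity = 0.8, coding = TRUE) {
  cut_pos <- if (is.numeric(guide)) as.integer(guide) else .locate_guide(reference_seq, guide)$cut_pos
  aln <- .align_global(read_seq, reference_seq)
  strs <- .aligned_strings(aln)
  pa <- strsplit(strs[1], "", fixed = TRUE)[[1]] # read
  sa <- strsplit(strs[2], "", fixed = TRUE)[[1]] # reference
  identity <- Biostrings::nmatch(aln) / length(pa)
  if (identity < min_identity) {
    stop("foreign amplicon: alignment identity ", sprintf("%.2f", identity),
         " below floor ", min_identity)
  }

  events <- .empty_events()
  n_noise <- 0L
  rpos <- 0L
  i <- 1L
  n <- length(pa)
  while (i <= n) {
    if (sa[i] == "-") { # insertion in read
      j <- i
      while (j <= n && sa[j] == "-") j <- j + 1L
      ins <- paste(pa[i:(j - 1L)], collapse = "")
      events <- rbind(events, data.frame(
        kind = "insertion", position = rpos - cut_pos, length = j - i,
        sequence = ins, stringsAsFactors = FALSE
      ))
      i <- j
    } else if (pa[i] == "-") { # deletion in read
      j <- i
      while (j <= n && pa[j] == "-") j <- j + 1L
      events <- rbind(events, data.frame(
        kind = "deletion", position = rpos + 1L - cut_pos, length = j - i,
        sequence = "", stringsAsFactors = FALSE
      ))
      rpos <- rpos + (j - i)
      i <- j
    } else {
      rpos <- rpos + 1L
      if (pa[i] != sa[i] && abs(rpos - cut_pos) > window) n_noise <- n_noise + 1L
      i <- i + 1L
    }
  }
  if (n_noise > max_noise_subs) {
    stop("foreign amplicon: ", n_noise, " substitutions outside the cut window")
  }
  events <- .normalize_events(events, reference_seq, cut_pos)
  frame <- if (!nrow(events) || !coding) {
    "none"
  } else {
    net <- sum(events$length[events$kind == "insertion"]) -
      sum(events$length[events$kind == "deletion"])
    if (net %% 3L == 0L) "in-frame" else "frameshift"
  }
  structure(
    list(
      events = events, wild_type = nrow(events) == 0L,
      frame_consequence = frame, n_noise_substitutions = n_noise,
      cut_pos = cut_pos
    ),
    class = "allele_call"
  )
}

#' @export
print.allele_call <- function(x, ...) {
  if (x$wild_type) {
    cat("<allele_call> wild type\n")
  } else {
    cat("<allele_call>", nrow(x$events), "event(s),", x$frame_consequence, "\n")
    print(x$events)
  }
  invisible(x)
}

#' Assign stable letter+number allele codes
#'
#' Alleles with identical event lists share one code. The wild type is
#' always coded `<letter>h`; mutant alleles are numbered in order of first
#' observation, so the mapping is a pure function of the ordered input and
#' an allele observed again in a later generation keeps its code.
#'
#' @param calls List of `allele_call` objects at one locus, in observation
#'   order.
#' @param letter Single-letter locus code (e.g. `"A"`).
#' @return Character vector of allele codes, one per call, with attribute
#'   `legend`: a named character vector mapping code -> event signature.
#' @export
name_alleles <- function(calls, letter = "A") {
  sigs <- vapply(calls, function(cl) .event_signature(cl$events), character(1))
  legend <- character(0)
  codes <- character(length(sigs))
  counter <- 0L
  for (i in seq_along(sigs)) {
    if (sigs[i] == "WT") {
      codes[i] <- paste0(letter, "h")
    } else if (sigs[i] %in% names(legend)) {
      codes[i] <- legend[[sigs[i]]]
    } else {
      counter <- counter + 1L
      codes[i] <- paste0(letter, counter)
      legend[[sigs[i]]] <- codes[i]
    }
  }
  out_legend <- if (length(legend)) {
    stats::setNames(names(legend), unname(legend))
  } else {
    character(0)
  }
  out_legend <- c(stats::setNames("WT", paste0(letter, "h")), out_legend)
  attr(codes, "legend") <- out_legend
  codes
}

#' Assess chimerism of a plant locus from plasmid-clone sequences
#'
#' Calls every clone against the reference, de-duplicates by event list and
#' reports the number of distinct mutant alleles, the fraction of clones
#' carrying any edit, and whether the locus looks chimeric (more than two
#' distinct alleles in total, which cannot arise from a fixed diploid
#' genotype). If any allele is supported by a single clone the spectrum may
#' be unsaturated and `saturation_warning` is set.
#'
#' @param clone_seqs Character vector of clone sequences (>= 1).
#' @param reference Wild-type reference sequence.
#' @param guide Protospacer or cut position, as in [call_alleles()].
#' @param ... Passed to [call_alleles()].
#' @return List: n_mutant_alleles, n_total_alleles, edited_fraction,
#'   chimeric, saturation_warning, calls (one `allele_call` per distinct
#'   allele), counts (clones per distinct allele signature).
#' @export
assess_chimerism <- function(clone_seqs, reference, guide, ...) {
  if (length(clone_seqs) < 1L) stop("need at least one clone sequence")
  calls <- lapply(clone_seqs, call_alleles, reference_seq = reference,
                  guide = guide, ...)
  sigs <- vapply(calls, function(cl) .event_signature(cl$events), character(1))
  counts <- table(sigs)
  distinct <- names(counts)
  n_mut <- sum(distinct != "WT")
  n_tot <- length(distinct)
  list(
    n_mutant_alleles = n_mut,
    n_total_alleles = n_tot,
    edited_fraction = mean(sigs != "WT"),
    chimeric = n_tot > 2L,
    saturation_warning = any(counts == 1L),
    calls = calls[match(distinct, sigs)],
    counts = counts
  )
}

#' Summarise a plant's genotype from coded alleles
#'
#' Classifies zygosity per locus and computes a composite mutant label over
#' a supplied locus set: a plant homozygous mutant at all three loci of the
#' set is a "triple mutant", etc. Wild-type alleles are recognised by the
#' `h` suffix.
#'
#' @param alleles Named list: locus -> character vector of 1--2 allele codes
#'   (a single code means homozygous).
#' @param transgenic Logical from the transgene PCR.
#' @param composite_over Character vector of loci the composite label is
#'   computed over (default: all loci).
#' @param chimeric Named logical per locus (loci with > 2 alleles must be
#'   flagged chimeric or an inconsistency error is raised).
#' @return List: zygosity (named character), label, n_homozygous_mutant,
#'   transgenic, alleles.
#' @export
genotype_plant <- function(alleles, transgenic = FALSE, composite_over = NULL,
                           chimeric = NULL) {
  if (is.null(composite_over)) composite_over <- names(alleles)
  zyg <- character(0)
  for (l in names(alleles)) {
    a <- unique(alleles[[l]])
    if (length(alleles[[l]]) > 2L && !isTRUE(chimeric[[l]])) {
      stop("locus ", l, " has more than 2 alleles but is not flagged chimeric")
    }
    if (length(alleles[[l]]) > 2L) {
      zyg[l] <- "chimeric"
      next
    }
    a2 <- if (length(alleles[[l]]) == 1L) rep(alleles[[l]], 2L) else alleles[[l]]
    wt <- grepl("h$", a2)
    zyg[l] <- if (all(wt)) {
      "homozygous wild type"
    } else if (any(wt)) {
      "heterozygous"
    } else if (a2[1] == a2[2]) {
      "homozygous mutant"
    } else {
      "biallelic mutant"
    }
  }
  n_hom <- sum(zyg[composite_over] == "homozygous mutant")
  any_mut <- any(zyg[composite_over] != "homozygous wild type")
  words <- c("single", "double", "triple", "quadruple", "quintuple",
             "sextuple", "septuple", "octuple")
  label <- if (n_hom >= 1L) {
    paste(if (n_hom <= length(words)) words[n_hom] else n_hom, "mutant")
  } else if (any_mut) {
    "segregating"
  } else {
    "wild type"
  }
  list(
    zygosity = zyg, label = label, n_homozygous_mutant = n_hom,
    transgenic = transgenic, alleles = alleles
  )
}
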