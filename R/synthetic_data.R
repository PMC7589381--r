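#' Describe a CRISPR target site to embed in a simulated family
#'
#' A planted site is a 20-nt protospacer followed by an NGG PAM that is
#' copied identically into every member of a simulated gene family, except
#' optionally one member that carries a single SNP at a chosen protospacer
#' position (counted from the PAM, position 1 = PAM-proximal). This mirrors
#' the situation in tetraploid gene families where one paralog differs from
#' the others at a single position of an otherwise conserved target.
#'
#' @param protospacer 20-nt DNA string.
#' @param pam 3-nt PAM, must match NGG.
#' @param snp_copy Optional index (1-based) of the family member carrying a SNP.
#' @param snp_position_from_pam Optional protospacer position 1..20 of the SNP,
#'   1 = PAM-proximal.
#' @return An object of class `planted_site`.
#' @export
planted_site <- function(protospacer, pam = "AGG", snp_copy = NULL,
                         snp_position_from_pam = NULL) {
  protospacer <- toupper(protospacer)
  pam <- toupper(pam)
  if (nchar(protospacer) != 20L) stop("protospacer must be exactly 20 nt")
  if (nchar(pam) != 3L || substr(pam, 2, 3) != "GG") stop("PAM must match NGG")
  if (!is.null(snp_copy) && is.null(snp_position_from_pam)) {
    stop("snp_position_from_pam must be set when snp_copy is set")
  }
  if (!is.null(snp_position_from_pam) &&
      (snp_position_from_pam < 1L || snp_position_from_pam > 20L)) {
    stop("snp_position_from_pam must lie in 1..20")
  }
  structure(
    list(
      protospacer = protospacer, pam = pam,
      snp_copy = snp_copy, snp_position_from_pam = snp_position_from_pam
    ),
    class = "planted_site"
  )
}

#' Simulate a polyploid gene family
#'
#' Generates `n_copies` paralogous coding sequences from a single random
#' ancestor by seeded point substitutions, such that every pairwise identity
#' (computed by global alignment, gaps counted as mismatches) lies inside
#' `identity_range`. In allotetraploid crops such as oilseed rape, gene
#' families typically hold two to eight members at roughly 89--99%
#' within-family identity, which the defaults reproduce.
#'
#' If `site` is given, the protospacer+PAM is embedded identically in all
#' copies at a fixed position, except that the designated SNP copy differs
#' from all others at exactly the requested protospacer position. No other
#' mutation is allowed inside the planted site.
#'
#' @param n_copies Number of family members (>= 2).
#' @param ancestral_length Length of the ancestral sequence in nt (>= 200).
#' @param identity_range Numeric pair: target range for all pairwise identities.
#' @param site Optional [planted_site()].
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @param name Family name used to label the copies (e.g. `"FAM1.A01"`).
#' @param max_tries Resampling attempts before declaring the range unreachable.
#' @return An object of class `gene_family`: list with `name`, `sequences`
#'   (named character vector), `identity_matrix`, `site` (with embedding
#'   coordinates) and `ancestor`.
#' @export
simulate_gene_family <- function(n_copies,
                                 ancestral_length = 900L,
                                 identity_range = c(0.89, 0.99),
                                 site = NULL,
                                 seed = 1L,
                                 name = "FAM",
                                 max_tries = 60L) {
  stopifnot(n_copies >= 2L, ancestral_length >= 200L)
  lo <- identity_range[1]; hi <- identity_range[2]
  if (lo > hi || lo < 0.85 || hi > 1) stop("identity_range must be within [0.85, 1] and low <= high")
  if (!is.null(site) && !inherits(site, "planted_site")) stop("site must be a planted_site")

  withr::with_seed(seed, {
    L <- as.integer(ancestral_length)
    ancestor <- random_dna(L)
    site_info <- NULL
    protected <- integer(0)
    if (!is.null(site)) {
      s <- max(31L, min(L - 100L, L %/% 2L - 11L)) # keep trace window downstream
      full <- paste0(site$protospacer, site$pam)
      substr(ancestor, s, s + 22L) <- full
      protected <- s:(s + 22L)
      site_info <- list(
        start = s, strand = "+",
        protospacer = site$protospacer, pam = site$pam,
        snp_copy = site$snp_copy,
        snp_position_from_pam = site$snp_position_from_pam
      )
    }
    free_pos <- setdiff(seq_len(L), protected)

    d_lo <- 1 - hi; d_hi <- 1 - lo
    labels <- paste0(
      name, ".",
      rep(c("A", "C"), length.out = n_copies),
      sprintf("%02d", ((seq_len(n_copies) - 1L) %/% 2L) + 1L)
    )

    for (try in seq_len(max_tries)) {
      if (d_hi == 0) {
        seqs <- rep(ancestor, n_copies)
      } else {
        # per-copy divergence; pairwise divergence is approximately the sum
        margin <- 0.05 * (d_hi - d_lo)
        u <- stats::runif(n_copies, d_lo / 2 + margin, d_hi / 2 - margin)
        n_sub <- pmin(round(u * L), length(free_pos))
        if (any(round((d_hi / 2) * L) == 0) && d_hi > 0) {
          stop("identity range unreachable at this sequence length")
        }
        seqs <- vapply(seq_len(n_copies), function(i) {
          s <- ancestor
          pos <- sample(free_pos, n_sub[i])
          for (p in pos) s <- .subst_at(s, p, .other_base(substr(s, p, p)))
          s
        }, character(1))
      }
      names(seqs) <- labels
      if (!is.null(site_info) && !is.null(site_info$snp_copy)) {
        p <- site_info$start + 20L - site_info$snp_position_from_pam
        old <- substr(seqs[[site_info$snp_copy]], p, p)
        seqs[[site_info$snp_copy]] <- .subst_at(seqs[[site_info$snp_copy]], p, .other_base(old))
      }
      idm <- pairwise_identity_matrix(seqs)
      off <- idm[upper.tri(idm)]
      if (all(off >= lo - 1e-12 & off <= hi + 1e-12)) {
        return(structure(
          list(
            name = name, sequences = seqs, identity_matrix = idm,
            site = site_info, ancestor = ancestor
          ),
          class = "gene_family"
        ))
      }
    }
  })
  stop("identity range unreachable at this sequence length (resampling exhausted)")
}

#' @export
print.gene_family <- function(x, ...) {
  cat("<gene_family>", x$name, "-", length(x$sequences), "members,",
      nchar(x$sequences[[1]]), "nt\n")
  off <- x$identity_matrix[upper.tri(x$identity_matrix)]
  if (length(off)) {
    cat("  pairwise identity:", sprintf("%.3f", min(off)), "-",
        sprintf("%.3f", max(off)), "\n")
  }
  if (!is.null(x$site)) {
    cat("  planted site at", x$site$start, "strand", x$site$strand, "\n")
  }
  invisible(x)
}

#' Default NHEJ indel-size spectrum
#'
#' NHEJ repair of Cas9 cuts produces predominantly small indels; the default
#' places 0.3 probability on a +1 insertion and spreads 0.7 over deletions
#' of 1..10 bp with geometrically decaying weight (ratio 0.5).
#'
#' @param insertion_probs Named numeric, names are positive indel sizes.
#' @param deletion_probs Named numeric, names are negative indel sizes.
#' @return An `indel_spectrum`: named numeric vector of probabilities summing
#'   to 1, names are signed indel sizes.
#' @export
indel_spectrum <- function(insertion_probs = c("1" = 0.3),
                           deletion_probs = {
                             w <- 0.5^(0:9); stats::setNames(0.7 * w / sum(w), -(1:10))
                           }) {
  p <- c(insertion_probs, deletion_probs)
  sizes <- as.integer(names(p))
  if (any(sizes == 0L)) stop("indel sizes must be nonzero")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) stop("probabilities must be nonnegative and sum to 1")
  structure(stats::setNames(as.numeric(p), sizes), class = "indel_spectrum")
}

# Locate a protospacer+NGG in a locus; returns list(start, strand, cut_pos)
# where cut_pos is the forward-strand base index immediately 5' of the
# blunt cut (3 bp from the PAM).
.locate_guide <- function(locus_seq, protospacer) {
  protospacer <- toupper(protospacer)
  hit <- regexpr(protospacer, locus_seq, fixed = TRUE)
  if (hit > 0) {
    s <- as.integer(hit)
    pam <- substr(locus_seq, s + 20L, s + 22L)
    if (substr(pam, 2, 3) == "GG") {
      return(list(start = s, strand = "+", cut_pos = s + 16L))
    }
  }
  rc <- revcomp(protospacer)
  hit <- regexpr(rc, locus_seq, fixed = TRUE)
  if (hit > 0) {
    s <- as.integer(hit) # protospacer (rc) occupies s..s+19, PAM at s-3..s-1
    if (s >= 4L) {
      pam_rc <- revcomp(substr(locus_seq, s - 3L, s - 1L))
      if (substr(pam_rc, 2, 3) == "GG") {
        return(list(start = s, strand = "-", cut_pos = s + 2L))
      }
    }
  }
  stop("guide does not map onto the locus with an NGG PAM")
}

#' Simulate NHEJ edit outcomes at a Cas9 cut site
#'
#' Returns `n_alleles` distinct mutant sequences, each the locus carrying a
#' single indel drawn from `spectrum` and placed at the cut site (blunt cut
#' 3 bp upstream of the PAM). Distinctness is enforced by resampling;
#' deletions of a given size at a fixed cut are identical, so a spectrum
#' with a single deletion size supports only one distinct allele.
#'
#' @param locus_seq Wild-type locus sequence.
#' @param guide 20-nt protospacer string present in `locus_seq` next to an
#'   NGG PAM (either strand), or a list with `start`, `strand` and `cut_pos`.
#' @param n_alleles Number of distinct mutant alleles (0..12).
#' @param spectrum An [indel_spectrum()].
#' @param seed Integer seed.
#' @return Character vector of mutant sequences; attribute `events` holds the
#'   left-normalised event table for each allele (as produced by
#'   [call_alleles()]), and attribute `cut_pos` the cut coordinate.
#' @export
simulate_nhej_alleles <- function(locus_seq, guide, n_alleles,
                                  spectrum = indel_spectrum(), seed = 1L) {
  stopifnot(n_alleles >= 0L, n_alleles <= 12L)
  if (n_alleles == 0L) return(character(0))
  if (!inherits(spectrum, "indel_spectrum")) spectrum <- indel_spectrum()
  loc <- if (is.character(guide)) .locate_guide(locus_seq, guide) else guide
  cut <- loc$cut_pos
  sizes <- as.integer(names(spectrum))

  withr::with_seed(seed, {
    alleles <- character(0)
    events <- list()
    seen <- character(0)
    tries <- 0L
    max_tries <- 200L * n_alleles
    while (length(alleles) < n_alleles) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("indel spectrum too small to yield ", n_alleles, " distinct alleles")
      }
      k <- sample(sizes, 1L, prob = spectrum)
      if (k < 0) {
        len <- -k
        if (cut + len > nchar(locus_seq)) next
        seq <- paste0(substr(locus_seq, 1, cut), substr(locus_seq, cut + len + 1L, nchar(locus_seq)))
        ev <- data.frame(
          kind = "deletion", position = 1L, length = len,
          sequence = "", stringsAsFactors = FALSE
        )
      } else {
        ins <- random_dna(k)
        seq <- paste0(substr(locus_seq, 1, cut), ins, substr(locus_seq, cut + 1L, nchar(locus_seq)))
        ev <- data.frame(
          kind = "insertion", position = 0L, length = k,
          sequence = ins, stringsAsFactors = FALSE
        )
      }
      ev <- .normalize_events(ev, locus_seq, cut)
      sig <- .event_signature(ev)
      if (sig %in% seen) next
      seen <- c(seen, sig)
      alleles <- c(alleles, seq)
      events[[length(alleles)]] <- ev
    }
    structure(alleles, events = events, cut_pos = cut)
  })
}

#' Simulate a four-channel Sanger-like chromatogram
#'
#' Each base contributes a Gaussian peak (height 1, sd = spacing/3) to its
#' channel at a fixed peak spacing; a mixed trace is the weighted sum of the
#' per-allele traces plus seeded Gaussian noise, clipped at zero. Shorter
#' alleles are zero-padded to the longest trace.
#'
#' @param allele_seqs Character vector of sequences in the mixture.
#' @param weights Nonnegative weights summing to 1, one per allele.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Integer seed.
#' @param spacing Grid points per base (default 4).
#' @return A `trace_set`: list with `intensities` (positions x 4 matrix,
#'   columns A/C/G/T), `spacing`, `n_bases` and `basecalls` (argmax channel
#'   at each peak centre).
#' @export
simulate_chromatogram <- function(allele_seqs, weights, noise_sd = 0,
                                  seed = 1L, spacing = 4L) {
  if (length(allele_seqs) == 0L) stop("empty allele list")
  if (length(weights) != length(allele_seqs)) stop("weights and alleles differ in length")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be nonnegative and sum to 1")
  }
  n_bases <- max(nchar(allele_seqs))
  npos <- n_bases * spacing
  pos <- seq_len(npos)
  sd <- spacing / 3

  mix <- matrix(0, npos, 4L, dimnames = list(NULL, DNA_BASES))
  for (a in seq_along(allele_seqs)) {
    b <- strsplit(allele_seqs[[a]], "", fixed = TRUE)[[1]]
    for (i in seq_along(b)) {
      centre <- (i - 0.5) * spacing
      lo <- max(1L, floor(centre - 4 * sd)); hi <- min(npos, ceiling(centre + 4 * sd))
      idx <- lo:hi
      mix[idx, b[i]] <- mix[idx, b[i]] +
        weights[a] * exp(-((idx - centre)^2) / (2 * sd^2))
    }
  }
  if (noise_sd > 0) {
    mix <- withr::with_seed(seed, mix + matrix(stats::rnorm(length(mix), 0, noise_sd), nrow(mix)))
    mix[mix < 0] <- 0
  }
  structure(
    list(
      intensities = mix, spacing = spacing, n_bases = n_bases,
      basecalls = .base_call(mix, spacing, n_bases)
    ),
    class = "trace_set"
  )
}

.base_call <- function(intensities, spacing, n_bases) {
  calls <- vapply(seq_len(n_bases), function(i) {
    r <- max(1L, min(nrow(intensities), round((i - 0.5) * spacing)))
    DNA_BASES[which.max(intensities[r, ])]
  }, character(1))
  paste(calls, collapse = "")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set>", x$n_bases, "bases at spacing", x$spacing, "\n")
  invisible(x)
}

#' Construct a plant genotype
#'
#' @param plant_id Plant identifier.
#' @param alleles Named list, locus -> character vector of allele codes
#'   observed in the plant (more than 2 marks a chimera).
#' @param germline Optional named list giving the allele subset actually
#'   present in the germ line of a chimeric plant (defaults to `alleles`,
#'   truncated to the values present). Loci absent from the list transmit
#'   from `alleles`.
#' @param transgene_copies Copies (0/1/2) at each of one or more unlinked
#'   T-DNA insertion loci; a single hemizygous insertion is `1L`.
#' @param generation Generation label such as `"T1"`.
#' @param parent_id Optional parent identifier.
#' @return Object of class `plant_genotype`.
#' @export
plant_genotype <- function(plant_id, alleles, germline = NULL,
                           transgene_copies = 0L, generation = "T1",
                           parent_id = NA_character_) {
  stopifnot(is.list(alleles), !is.null(names(alleles)))
  if (any(transgene_copies < 0L | transgene_copies > 2L)) stop("transgene copies in 0..2")
  structure(
    list(
      plant_id = plant_id, parent_id = parent_id, generation = generation,
      alleles = alleles,
      germline = if (is.null(germline)) alleles else utils::modifyList(alleles, germline),
      transgene_copies = as.integer(transgene_copies)
    ),
    class = "plant_genotype"
  )
}

#' @export
print.plant_genotype <- function(x, ...) {
  cat("<plant_genotype>", x$plant_id, x$generation,
      if (any(x$transgene_copies > 0)) "[transgenic]" else "[non-transgenic]", "\n")
  for (l in names(x$alleles)) cat(" ", l, ":", paste(x$alleles[[l]], collapse = "/"), "\n")
  invisible(x)
}

.next_generation_label <- function(gen) {
  n <- suppressWarnings(as.integer(sub("^T", "", gen)))
  if (is.na(n)) stop("generation labels must look like 'T1'")
  paste0("T", n + 1L)
}

#' Simulate a selfing pedigree
#'
#' Selfs every selected plant at each generation. Per locus, each offspring
#' receives two gametes drawn independently from the parent's germline
#' allele set (Mendelian sampling for a fixed heterozygote; a chimeric
#' founder transmits only its configured germline subset, so somatic-only
#' alleles are lost). Each hemizygous T-DNA insertion is transmitted to 3/4
#' of selfed offspring (copies segregate 1:2:1). While a transgene copy is
#' present, Cas9 remains active and each wild-type allele can be replaced by
#' a new de novo allele with probability `de_novo_rate` per locus.
#'
#' @param founder A [plant_genotype()].
#' @param n_generations Number of selfing rounds (>= 1).
#' @param offspring_per_plant Offspring per selfed plant.
#' @param seed Integer seed.
#' @param de_novo_rate Per-locus probability of a de novo edit in a
#'   transgenic offspring.
#' @param select Optional function(list of plant_genotype) -> subset to self
#'   at each generation (default: self all).
#' @return A `pedigree`: list with `plants` (named list of plant_genotype)
#'   and a long-format `table` (plant, parent, generation, locus, alleles,
#'   transgene status).
#' @export
simulate_pedigree <- function(founder, n_generations, offspring_per_plant,
                              seed = 1L, de_novo_rate = 0, select = NULL) {
  if (n_generations < 1L) stop("n_generations must be >= 1")
  stopifnot(inherits(founder, "plant_genotype"))
  loci <- names(founder$alleles)
  de_novo_counter <- stats::setNames(rep(100L, length(loci)), loci)

  withr::with_seed(seed, {
    plants <- stats::setNames(list(founder), founder$plant_id)
    current <- list(founder)
    for (g in seq_len(n_generations)) {
      parents <- if (is.null(select)) current else select(current)
      nxt <- list()
      for (par in parents) {
        for (o in seq_len(offspring_per_plant)) {
          id <- paste0(par$plant_id, ".", o)
          alle <- list()
          for (l in loci) {
            pool <- par$germline[[l]]
            a <- c(sample(pool, 1L), sample(pool, 1L))
            alle[[l]] <- sort(a)
          }
          tg <- vapply(par$transgene_copies, function(cp) {
            sum(stats::runif(2L) < cp / 2)
          }, integer(1))
          if (de_novo_rate > 0 && any(tg > 0L)) {
            for (l in loci) {
              wt <- grepl("h$", alle[[l]])
              if (any(wt) && stats::runif(1) < de_novo_rate) {
                de_novo_counter[l] <- de_novo_counter[l] + 1L
                letter <- sub("h$", "", alle[[l]][which(wt)[1]])
                alle[[l]][which(wt)[1]] <- paste0(letter, de_novo_counter[l])
              }
            }
          }
          child <- plant_genotype(
            plant_id = id, alleles = alle,
            transgene_copies = tg,
            generation = .next_generation_label(par$generation),
            parent_id = par$plant_id
          )
          nxt[[length(nxt) + 1L]] <- child
          plants[[id]] <- child
        }
      }
      current <- nxt
    }
    structure(list(plants = plants, table = .pedigree_table(plants)), class = "pedigree")
  })
}

.pedigree_table <- function(plants) {
  rows <- lapply(plants, function(p) {
    do.call(rbind, lapply(names(p$alleles), function(l) {
      a <- p$alleles[[l]]
      data.frame(
        plant_id = p$plant_id, parent_id = p$parent_id,
        generation = p$generation, locus = l,
        allele1 = a[1], allele2 = if (length(a) >= 2) a[2] else a[1],
        allele_set = paste(a, collapse = "|"),
        transgene_copies = sum(p$transgene_copies),
        transgenic = any(p$transgene_copies > 0L),
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.pedigree <- function(x, ...) {
  gens <- table(vapply(x$plants, `[[`, character(1), "generation"))
  cat("<pedigree>", length(x$plants), "plants:",
      paste(names(gens), gens, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Specify phenotype simulation parameters
#'
#' @param control_means Named numeric: per-trait control mean (> 0).
#' @param effects Named list: genotype class -> named numeric multiplicative
#'   effect per trait (traits absent default to 1). Must include a class
#'   named `control` (all effects 1).
#' @param cv Coefficient of variation in (0, 1).
#' @param n_replicates Biological replicates per class (>= 2).
#' @param seed Integer seed.
#' @return Object of class `phenotype_effect_spec`.
#' @export
phenotype_effect_spec <- function(control_means, effects, cv = 0.08,
                                  n_replicates = 5L, seed = 1L) {
  if (any(control_means <= 0)) stop("control means must be positive")
  if (cv <= 0 || cv >= 1) stop("cv must lie in (0, 1)")
  if (n_replicates < 2L) stop("need at least 2 replicates")
  if (!"control" %in% names(effects)) stop("effects must include a 'control' class")
  for (e in effects) if (any(e <= 0)) stop("effects must be positive")
  structure(
    list(
      control_means = control_means, effects = effects,
      cv = cv, n_replicates = n_replicates, seed = seed
    ),
    class = "phenotype_effect_spec"
  )
}

#' Simulate a long-format phenotype table
#'
#' Each genotype class and trait receives `n_replicates` values drawn from
#' Normal(mean x effect, cv x mean x effect).
#'
#' @param spec A [phenotype_effect_spec()].
#' @return data.frame with columns plant_id, line, trait, replicate, value.
#' @export
simulate_phenotypes <- function(spec) {
  stopifnot(inherits(spec, "phenotype_effect_spec"))
  withr::with_seed(spec$seed, {
    rows <- list()
    for (cls in names(spec$effects)) {
      for (trait in names(spec$control_means)) {
        eff <- spec$effects[[cls]]
        mult <- if (trait %in% names(eff)) eff[[trait]] else 1
        m <- spec$control_means[[trait]] * mult
        vals <- stats::rnorm(spec$n_replicates, m, spec$cv * m)
        rows[[length(rows) + 1L]] <- data.frame(
          plant_id = paste0(cls, "_", seq_len(spec$n_replicates)),
          line = cls, trait = trait,
          replicate = seq_len(spec$n_replicates), value = vals,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
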