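#' Default configuration for the end-to-end demo
#'
#' Thresholds follow the design rules used throughout the package (GC
#' strictly above 40%, at most one SNP and only PAM-distal of protospacer
#' position 10, off-target scan at up to 2 mismatches with a mandatory GG),
#' and population sizes reflect a small greenhouse programme (tens of
#' plants genotyped per generation).
#'
#' @return Named list of configuration values.
#' @export
demo_config <- function() {
  list(
    gc_min = 40, max_mismatches = 1L, seed_boundary = 10L, offtarget_mm = 2L,
    alpha = 0.05,
    family_length = 900L, identity_range = c(0.90, 0.99),
    n_t2 = 50L, n_per_parent = 50L, n_select = 3L,
    de_novo_rate = 0.03, clones_per_locus = 30L,
    n_replicates = 5L, cv = 0.06
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

# Locate a protospacer on a locus allowing the configured SNP tolerance.
.locate_guide_fuzzy <- function(locus_seq, protospacer, max_mm = 1L) {
  ok <- try(.locate_guide(locus_seq, protospacer), silent = TRUE)
  if (!inherits(ok, "try-error")) return(ok)
  m <- Biostrings::matchPattern(Biostrings::DNAString(protospacer),
                                Biostrings::DNAString(locus_seq),
                                max.mismatch = max_mm)
  for (s in Biostrings::start(m)) {
    if (s + 22L <= nchar(locus_seq) &&
        substr(locus_seq, s + 21L, s + 22L) == "GG") {
      return(list(start = s, strand = "+", cut_pos = s + 16L))
    }
  }
  stop("guide does not map onto the locus")
}

# Rank plants for selfing: most required loci fixed homozygous mutant, then
# most loci carrying any mutant allele, then avoid transgene-homozygous
# lineages (they can never segregate the T-DNA away), then id.
.demo_select <- function(required_loci, n_keep) {
  force(required_loci); force(n_keep)
  function(plants) {
    score <- vapply(plants, function(p) {
      hom <- sum(vapply(required_loci, function(l) {
        a <- p$alleles[[l]]
        length(unique(a)) == 1L && !grepl("h$", a[1])
      }, logical(1)))
      mut <- sum(vapply(required_loci, function(l) {
        any(!grepl("h$", p$alleles[[l]]))
      }, logical(1)))
      tg_pen <- if (sum(p$transgene_copies) >= 2L) 1L else 0L
      hom * 100 + mut * 10 - tg_pen * 5
    }, numeric(1))
    ids <- vapply(plants, `[[`, character(1), "plant_id")
    plants[order(-score, ids)][seq_len(min(n_keep, length(plants)))]
  }
}

#' Run the full synthetic knockout workflow end to end
#'
#' Simulates a tetraploid two-family system, designs family-conserved
#' guides, simulates chimeric primary transformants and three generations of
#' selfing under a single hemizygous T-DNA insertion, genotypes plasmid
#' clones, decomposes a mixed trace, tests transgene segregation, selects
#' non-transgenic triple-homozygous plants, and runs the phenotype
#' statistics. Fully reproducible under `seed`; with `outdir` set, every
#' intermediate file is written with the seed and a config digest in its
#' header.
#'
#' @param seed Integer master seed.
#' @param outdir Optional output directory for the report bundle.
#' @param config Configuration list as from [demo_config()].
#' @return A report list with elements families, genome, discovery, guides,
#'   chimeras, founder, pedigree, segregation, tracking, decomposition,
#'   candidates, phenotypes, stats, config, seed.
#' @export
run_demo <- function(seed = 1L, outdir = NULL, config = demo_config()) {
  cfg <- utils::modifyList(demo_config(), config)
  required_loci <- c("A", "B", "G")

  ## -- gene families with a planted conserved target site ------------------
  fams <- .stage("simulate_families", {
    proto1 <- "TGCACGGATCTGAACGTCCA"
    proto2 <- "CATGGTCCGATAGCACTGGA"
    fam1 <- simulate_gene_family(
      4L, cfg$family_length, cfg$identity_range,
      site = planted_site(proto1, "TGG", snp_copy = 3L, snp_position_from_pam = 10L),
      seed = seed + 11L, name = "GF1"
    )
    fam2 <- simulate_gene_family(
      3L, cfg$family_length, cfg$identity_range,
      site = planted_site(proto2, "TGG", snp_copy = 3L, snp_position_from_pam = 10L),
      seed = seed + 12L, name = "GF2"
    )
    list(fam1 = fam1, fam2 = fam2)
  })

  ## -- genome: each member embedded in a background contig + decoys --------
  genome_parts <- .stage("build_genome", {
    withr::with_seed(seed + 13L, {
      contigs <- character(0)
      intervals <- list()
      for (fam in fams) {
        for (m in names(fam$sequences)) {
          bg <- random_dna(3000L)
          off <- sample(200:1500, 1L)
          contig <- paste0(substr(bg, 1, off), fam$sequences[[m]],
                           substr(bg, off + 1L, nchar(bg)))
          cn <- paste0("chr_", m)
          contigs[cn] <- contig
          intervals[[length(intervals) + 1L]] <- data.frame(
            member = m, contig = cn, start = off,
            end = off + nchar(fam$sequences[[m]]), strand = "+",
            stringsAsFactors = FALSE
          )
        }
      }
      contigs["decoy1"] <- random_dna(5000L)
      contigs["decoy2"] <- random_dna(5000L)
      list(genome = contigs, intervals = do.call(rbind, intervals))
    })
  })
  genome <- genome_parts$genome
  intervals <- genome_parts$intervals

  ## -- paralog discovery ----------------------------------------------------
  discovery <- .stage("paralog_discovery", {
    hits <- find_paralogs(fams$fam1$sequences[[1]], genome,
                          min_identity = 0.8, min_coverage = 0.8)
    all_seqs <- c(fams$fam1$sequences, fams$fam2$sequences)
    families <- group_families(all_seqs, within_threshold = 0.85)
    idm <- pairwise_identity_matrix(all_seqs)
    list(hits = hits, families = families, identity_matrix = idm,
         tree = build_distance_tree(idm))
  })

  ## -- guide design ----------------------------------------------------------
  guides <- .stage("guide_design", {
    pick <- function(fam, target_members) {
      iv <- intervals[intervals$member %in% names(fam$sequences), , drop = FALSE]
      des <- design_guides(fam, genome, family_intervals = iv,
                           gc_min = cfg$gc_min, max_mismatches = cfg$max_mismatches,
                           seed_boundary = cfg$seed_boundary,
                           offtarget_mm = cfg$offtarget_mm)
      if (!nrow(des)) stop("no guide accepted for ", fam$name)
      # prefer guides perfectly conserved in the members to be knocked out
      clean <- vapply(seq_len(nrow(des)), function(i) {
        prof <- des$profile[[i]]
        all(vapply(target_members, function(m) {
          is.null(prof[[m]]) || length(prof[[m]]$mismatches) == 0L
        }, logical(1)))
      }, logical(1))
      des2 <- des[clean, , drop = FALSE]
      if (!nrow(des2)) stop("no guide conserved in the target members of ", fam$name)
      out <- des2[1, , drop = FALSE]
      attr(out, "all") <- des
      out
    }
    g1 <- pick(fams$fam1, names(fams$fam1$sequences)[1:2])
    g2 <- pick(fams$fam2, names(fams$fam2$sequences)[1:2])
    list(fam1 = g1, fam2 = g2)
  })

  ## -- T1 chimeras: simulate NHEJ alleles and genotype plasmid clones ------
  loci <- list(
    A = list(seq = fams$fam1$sequences[[1]], proto = guides$fam1$protospacer, n = 4L),
    B = list(seq = fams$fam1$sequences[[2]], proto = guides$fam1$protospacer, n = 3L),
    E = list(seq = fams$fam2$sequences[[1]], proto = guides$fam2$protospacer, n = 4L),
    G = list(seq = fams$fam2$sequences[[2]], proto = guides$fam2$protospacer, n = 3L)
  )
  chimeras <- .stage("t1_chimeras", {
    out <- list()
    i <- 0L
    for (l in names(loci)) {
      i <- i + 1L
      loc <- loci[[l]]
      g <- .locate_guide_fuzzy(loc$seq, loc$proto)
      alleles <- simulate_nhej_alleles(loc$seq, g, loc$n, seed = seed + 20L + i)
      # clone library: edited-to-non-edited ratio deliberately low
      w <- c(0.55, rep(0.45 / loc$n, loc$n))
      clones <- withr::with_seed(seed + 30L + i, {
        idx <- sample(seq_len(loc$n + 1L), cfg$clones_per_locus, replace = TRUE, prob = w)
        c(loc$seq, alleles)[idx]
      })
      chim <- assess_chimerism(clones, loc$seq, g$cut_pos)
      codes <- name_alleles(chim$calls, letter = l)
      out[[l]] <- list(
        locus = l, cut_pos = g$cut_pos, alleles = alleles,
        chimerism = chim, codes = codes,
        n_distinct_mutant = chim$n_mutant_alleles
      )
    }
    out
  })

  ## -- founder and selfing pedigree ----------------------------------------
  founder <- .stage("founder", {
    somatic <- lapply(chimeras, function(ch) unique(ch$codes))
    # germ line: one edited + one wild-type allele at A, B and G; the E
    # edits are somatic only and are not transmitted
    germ <- list(
      A = c(grep("h$", somatic$A, value = TRUE, invert = TRUE)[1], "Ah"),
      B = c(grep("h$", somatic$B, value = TRUE, invert = TRUE)[1], "Bh"),
      E = "Eh",
      G = c(grep("h$", somatic$G, value = TRUE, invert = TRUE)[1], "Gh")
    )
    plant_genotype("itpk_C1", alleles = somatic, germline = germ,
                   transgene_copies = 1L, generation = "T1")
  })
  ped <- .stage("pedigree", {
    simulate_pedigree(
      founder, n_generations = 3L, offspring_per_plant = cfg$n_per_parent,
      seed = seed + 40L, de_novo_rate = cfg$de_novo_rate,
      select = .demo_select(required_loci, cfg$n_select)
    )
  })

  ## -- transgene segregation in T2 ------------------------------------------
  segregation <- .stage("segregation", {
    t2 <- Filter(function(p) p$generation == "T2", ped$plants)
    n_pos <- sum(vapply(t2, function(p) any(p$transgene_copies > 0L), logical(1)))
    segregation_test(n_pos, length(t2) - n_pos, ratio = c(3, 1), alpha = cfg$alpha)
  })

  tracking <- .stage("allele_tracking", track_alleles(ped))

  ## -- trace decomposition at locus A ---------------------------------------
  decomposition <- .stage("trace_decomposition", {
    la <- chimeras$A
    w <- c(0.4, rep(0.6 / length(la$alleles), length(la$alleles)))
    control <- simulate_chromatogram(loci$A$seq, 1, noise_sd = 0, seed = seed + 50L)
    sample_tr <- simulate_chromatogram(c(loci$A$seq, la$alleles), w,
                                       noise_sd = 0.03, seed = seed + 51L)
    dec <- decompose_trace(sample_tr, control, cut_base = la$cut_pos)
    truth_sizes <- vapply(attr(la$alleles, "events"), function(ev) {
      if (ev$kind[1] == "deletion") -ev$length[1] else ev$length[1]
    }, integer(1))
    list(result = dec, true_sizes = c(0L, truth_sizes), true_weights = w,
         control = control, sample = sample_tr)
  })

  ## -- selection of non-transgenic triple homozygotes ------------------------
  candidates <- .stage("selection", {
    sel <- select_candidates(ped, required_loci, require_nontransgenic = TRUE,
                             generation = "T4")
    list(T4 = sel, found_by_T4 = nrow(sel) > 0L)
  })

  ## -- phenotypes ------------------------------------------------------------
  phen <- .stage("phenotypes", {
    spec <- phenotype_effect_spec(
      control_means = c(phytic_acid = 32, inorganic_p = 1.1, oil_pct = 45),
      effects = list(
        control = c(phytic_acid = 1),
        double_mutant = c(phytic_acid = 0.90, inorganic_p = 1.3),
        triple_mutant_a = c(phytic_acid = 0.728, inorganic_p = 3.0),
        triple_mutant_b = c(phytic_acid = 0.647, inorganic_p = 3.0)
      ),
      cv = cfg$cv, n_replicates = cfg$n_replicates, seed = seed + 60L
    )
    tab <- simulate_phenotypes(spec)
    pa <- anova_tukey(tab, "phytic_acid", alpha = cfg$alpha)
    pi <- anova_tukey(tab, "inorganic_p", alpha = cfg$alpha)
    ctrl_pa <- mean(tab$value[tab$line == "control" & tab$trait == "phytic_acid"])
    tb_pa <- mean(tab$value[tab$line == "triple_mutant_b" & tab$trait == "phytic_acid"])
    ctrl_pi <- mean(tab$value[tab$line == "control" & tab$trait == "inorganic_p"])
    tb_pi <- mean(tab$value[tab$line == "triple_mutant_b" & tab$trait == "inorganic_p"])
    list(
      table = tab, pa = pa, pi = pi,
      pa_change = percent_change(tb_pa, ctrl_pa),
      pi_change = percent_change(tb_pi, ctrl_pi)
    )
  })

  report <- list(
    families = fams, genome = genome, intervals = intervals,
    discovery = discovery, guides = guides, chimeras = chimeras,
    founder = founder, pedigree = ped, segregation = segregation,
    tracking = tracking, decomposition = decomposition,
    candidates = candidates, phenotypes = phen,
    config = cfg, seed = seed
  )
  if (!is.null(outdir)) .write_demo_bundle(report, outdir)
  report
}

# Simple order-sensitive digest of the configuration, recorded in output headers.
.config_digest <- function(cfg, seed) {
  s <- paste(names(cfg), vapply(cfg, function(x) paste(x, collapse = ","), character(1)),
             collapse = ";", sep = "=")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max + seed)
}

.write_demo_bundle <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(paste0("seed=", report$seed),
           paste0("config=", .config_digest(report$config, report$seed)))
  write_fasta(c(report$families$fam1$sequences, report$families$fam2$sequences),
              file.path(outdir, "families.fasta"))
  write_fasta(report$genome, file.path(outdir, "genome.fasta"))
  write_guide_tsv(rbind(report$guides$fam1, report$guides$fam2),
                  file.path(outdir, "guides.tsv"), header = hdr)
  write_pedigree_csv(report$pedigree, file.path(outdir, "pedigree.csv"), header = hdr)
  write_phenotype_csv(report$phenotypes$table, file.path(outdir, "phenotypes.csv"),
                      header = hdr)
  write_trace_tsv(report$decomposition$control, file.path(outdir, "trace_control.tsv"),
                  header = hdr)
  write_trace_tsv(report$decomposition$sample, file.path(outdir, "trace_sample.tsv"),
                  header = hdr)
  dec <- report$decomposition$result
  con <- file(file.path(outdir, "decomposition.tsv"), "w")
  for (h in hdr) writeLines(paste0("# ", h), con)
  utils::write.table(
    data.frame(indel_size = names(dec$frequencies), frequency = dec$frequencies),
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  close(con)
  summary_lines <- c(
    paste0("# seed=", report$seed),
    paste0("n_paralog_hits=", nrow(report$discovery$hits)),
    paste0("n_families=", length(report$discovery$families)),
    paste0("segregation_p=", signif(report$segregation$p_value, 4)),
    paste0("n_T4_candidates=", nrow(report$candidates$T4)),
    paste0("pa_change_pct=", signif(report$phenotypes$pa_change, 4)),
    paste0("pi_fold=", signif(attr(report$phenotypes$pi_change, "fold"), 4))
  )
  writeLines(summary_lines, file.path(outdir, "run_summary.txt"))
  invisible(outdir)
}
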