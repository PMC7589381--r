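#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a trace_set as a tab-separated four-channel table
#'
#' Columns: position, A, C, G, T. Metadata (spacing, n_bases, plus any
#' extra `header` lines such as the run seed) is stored in leading `#`
#' comment lines so the trace can be re-read losslessly.
#'
#' @param trace A `trace_set`.
#' @param path Output path.
#' @param header Optional character vector of extra comment lines.
#' @export
write_trace_tsv <- function(trace, path, header = character(0)) {
  stopifnot(inherits(trace, "trace_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines(paste0("# spacing=", trace$spacing), con)
  writeLines(paste0("# n_bases=", trace$n_bases), con)
  df <- data.frame(position = seq_len(nrow(trace$intensities)),
                   trace$intensities, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trace table written by [write_trace_tsv()]
#'
#' @param path Input path.
#' @return A `trace_set`.
#' @export
read_trace_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (!length(m)) stop("trace table lacks '", key, "' metadata")
    as.integer(sub(paste0("^# ", key, "="), "", m[1]))
  }
  spacing <- get_meta("spacing")
  n_bases <- get_meta("n_bases")
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE)
  m <- as.matrix(df[, c("A", "C", "G", "T")])
  structure(
    list(intensities = m, spacing = spacing, n_bases = n_bases,
         basecalls = .base_call(m, spacing, n_bases)),
    class = "trace_set"
  )
}

#' Write a pedigree's long-format table to CSV
#'
#' @param pedigree A `pedigree`.
#' @param path Output path.
#' @param header Optional `#` comment lines (e.g. the run seed).
#' @export
write_pedigree_csv <- function(pedigree, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.csv(pedigree$table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pedigree CSV back into a `pedigree` object
#'
#' Reconstructs plant genotypes from the long-format table (chimeric allele
#' sets are restored from the `allele_set` column).
#'
#' @param path Input path.
#' @return A `pedigree`.
#' @export
read_pedigree_csv <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  plants <- list()
  for (pid in unique(tab$plant_id)) {
    rows <- tab[tab$plant_id == pid, , drop = FALSE]
    alle <- stats::setNames(
      lapply(seq_len(nrow(rows)), function(i) strsplit(rows$allele_set[i], "|", fixed = TRUE)[[1]]),
      rows$locus
    )
    plants[[pid]] <- plant_genotype(
      plant_id = pid, alleles = alle,
      transgene_copies = rows$transgene_copies[1],
      generation = rows$generation[1],
      parent_id = if (is.na(rows$parent_id[1]) || rows$parent_id[1] == "") NA_character_ else rows$parent_id[1]
    )
  }
  structure(list(plants = plants, table = tab), class = "pedigree")
}

#' Write a phenotype table to CSV
#'
#' @param table Long-format phenotype data.frame.
#' @param path Output path.
#' @param header Optional `#` comment lines.
#' @export
write_phenotype_csv <- function(table, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.csv(table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype CSV
#'
#' @param path Input path.
#' @return data.frame.
#' @export
read_phenotype_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a guide design report TSV
#'
#' One row per accepted candidate: protospacer, PAM, reference paralog,
#' position, strand, GC%, per-paralog mismatch string, off-target count.
#'
#' @param guides Ranked candidates from [design_guides()].
#' @param path Output path.
#' @param header Optional `#` comment lines.
#' @export
write_guide_tsv <- function(guides, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  mm_string <- vapply(seq_len(nrow(guides)), function(i) {
    prof <- guides$profile[[i]]
    paste(vapply(names(prof), function(m) {
      mm <- prof[[m]]$mismatches
      paste0(m, ":", if (length(mm)) paste(mm, collapse = ",") else "-")
    }, character(1)), collapse = ";")
  }, character(1))
  df <- guides[, c("reference_paralog", "strand", "start", "cut_pos",
                   "protospacer", "pam", "gc_percent", "total_mismatches",
                   "off_target_hits"), drop = FALSE]
  df$mismatch_profile <- mm_string
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
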