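#' Transformation efficiency
#'
#' Efficiency = independent transgenic plants / explants x 100, reported to
#' one decimal place.
#'
#' @param n_independent_transgenics Count of independent transgenic events.
#' @param n_explants Total explants co-cultivated (> 0).
#' @return Percentage rounded to one decimal.
#' @export
transformation_efficiency <- function(n_independent_transgenics, n_explants) {
  if (n_explants <= 0L) stop("zero explants")
  if (n_independent_transgenics < 0L || n_independent_transgenics > n_explants) {
    stop("transgenic count must lie in 0..n_explants")
  }
  round(100 * n_independent_transgenics / n_explants, 1)
}

#' Signed percent change of a treatment mean relative to a control mean
#'
#' Negative values are reductions; a threefold increase corresponds to
#' +200%. `attr(,"fold")` carries the fold change 1 + change/100.
#'
#' @param treatment_mean Treatment mean.
#' @param control_mean Control mean (> 0).
#' @return Signed percent change, with attribute `fold`.
#' @export
percent_change <- function(treatment_mean, control_mean) {
  if (control_mean <= 0) stop("control mean must be positive")
  chg <- 100 * (treatment_mean - control_mean) / control_mean
  attr(chg, "fold") <- 1 + chg / 100
  chg
}

# Compact letter display by insert-and-absorb over significant pairs.
# groups: character vector ordered by decreasing mean; sig: data.frame with
# columns g1, g2 of significantly different pairs.
.compact_letters <- function(groups, sig) {
  cols <- list(groups)
  if (nrow(sig)) {
    for (r in seq_len(nrow(sig))) {
      a <- sig$g1[r]; b <- sig$g2[r]
      nxt <- list()
      for (col in cols) {
        if (a %in% col && b %in% col) {
          nxt[[length(nxt) + 1L]] <- setdiff(col, a)
          nxt[[length(nxt) + 1L]] <- setdiff(col, b)
        } else {
          nxt[[length(nxt) + 1L]] <- col
        }
      }
      nxt <- nxt[lengths(nxt) > 0L]
      # absorb: drop any column whose group set is contained in another's
      keep <- rep(TRUE, length(nxt))
      for (i in seq_along(nxt)) {
        for (j in seq_along(nxt)) {
          if (i != j && keep[i] && keep[j] && all(nxt[[i]] %in% nxt[[j]]) &&
              (length(nxt[[i]]) < length(nxt[[j]]) || i > j)) {
            keep[i] <- FALSE
          }
        }
      }
      cols <- nxt[keep]
    }
  }
  # deterministic letter order: by first (highest-mean) member, then size
  first_idx <- vapply(cols, function(col) min(match(col, groups)), numeric(1))
  cols <- cols[order(first_idx, -lengths(cols))]
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (ci in seq_along(cols)) {
    for (g in cols[[ci]]) {
      letters_out[g] <- paste0(letters_out[g], letters[ci])
    }
  }
  letters_out
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits a fixed-effects one-way ANOVA of the trait on line, runs Tukey's
#' honestly-significant-difference test on all pairwise line contrasts, and
#' summarises the pairwise decisions as compact letters: lines sharing a
#' letter are not significantly different at `alpha`. If the table carries a
#' `tech_rep` column, technical replicates are averaged to plant means
#' first, matching the greenhouse design of biological replicates measured
#' repeatedly.
#'
#' @param table Long-format phenotype data.frame with columns `line`,
#'   `trait`, `value` (and optionally `plant_id`, `tech_rep`).
#' @param trait Trait to analyse.
#' @param alpha Significance level (default 0.05).
#' @return A `comparison_result`: list with `trait`, `anova` (F, df, p),
#'   `tukey` (pairwise table with adjusted p-values), `letters`, `means`,
#'   `alpha`.
#' @export
anova_tukey <- function(table, trait, alpha = 0.05) {
  d <- table[table$trait == trait, , drop = FALSE]
  if (!nrow(d)) stop("trait not found: ", trait)
  if (!is.null(d$tech_rep) && !is.null(d$plant_id)) {
    d <- stats::aggregate(value ~ line + plant_id, data = d, FUN = mean)
  }
  counts <- base::table(d$line)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning("excluding line(s) with < 2 replicates: ", paste(small, collapse = ", "))
    d <- d[!d$line %in% small, , drop = FALSE]
  }
  if (length(unique(d$line)) < 2L) stop("need at least 2 lines with >= 2 replicates")
  d$line <- factor(d$line)

  fit <- stats::aov(value ~ line, data = d)
  s <- summary(fit)[[1]]
  an <- list(
    F = s[["F value"]][1], df1 = as.integer(s[["Df"]][1]),
    df2 = as.integer(s[["Df"]][2]), p = s[["Pr(>F)"]][1]
  )
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$line
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  tukey <- data.frame(
    g1 = pairs[, 1], g2 = pairs[, 2],
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"], stringsAsFactors = FALSE
  )
  rownames(tukey) <- NULL
  means <- stats::aggregate(value ~ line, data = d, FUN = mean)
  sds <- stats::aggregate(value ~ line, data = d, FUN = stats::sd)
  ns <- stats::aggregate(value ~ line, data = d, FUN = length)
  means <- data.frame(line = as.character(means$line), mean = means$value,
                      sd = sds$value, n = ns$value, stringsAsFactors = FALSE)
  ord <- means$line[order(-means$mean)]
  sig <- tukey[tukey$p_adj < alpha, c("g1", "g2"), drop = FALSE]
  letters_out <- .compact_letters(ord, sig)
  means$letters <- letters_out[means$line]
  structure(
    list(trait = trait, anova = an, tukey = tukey,
         letters = letters_out, means = means, alpha = alpha),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>", x$trait,
      sprintf("F(%d, %d) = %.3f, p = %.4g\n", x$anova$df1, x$anova$df2,
              x$anova$F, x$anova$p))
  print(x$means, row.names = FALSE)
  invisible(x)
}
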