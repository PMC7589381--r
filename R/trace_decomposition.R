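#' Decompose a mixed Sanger-like trace into indel-size frequencies
#'
#' TIDE-style non-negative decomposition: candidate basis traces are built
#' by shifting the wild-type control trace by -`max_indel`..+`max_indel`
#' bases downstream of the cut, and the mixture weights are estimated by
#' non-negative least squares over an analysis window of bases downstream of
#' the cut. For insertion shifts the inserted bases are unknown; the window
#' starts at least `max_indel` bases past the cut so those positions lie
#' outside the fit (the single boundary base of the largest insertion is
#' modelled as an uninformative flat channel signal).
#'
#' @param sample A `trace_set` for the edited (possibly mixed) sample.
#' @param control A `trace_set` for the wild-type control; its base calls
#'   must match the sample's upstream of the cut.
#' @param cut_base Base index (1-based) immediately 5' of the cut.
#' @param max_indel Largest indel size modelled (default 10).
#' @param window Analysis window in bases downstream of the cut, default
#'   `c(10, 60)`; the lower bound is raised to `max_indel` if needed.
#' @return A `decomposition`: list with `frequencies` (named by signed indel
#'   size, nonnegative, summing to 1), `raw_weights`, `r_squared`, `window`
#'   and `low_fit` (TRUE when R^2 < 0.9).
#' @export
decompose_trace <- function(sample, control, cut_base, max_indel = 10L,
                            window = c(10L, 60L)) {
  stopifnot(inherits(sample, "trace_set"), inherits(control, "trace_set"))
  if (sample$spacing != control$spacing) stop("sample and control spacing differ")
  spacing <- sample$spacing
  window <- as.integer(window)
  if (window[1] < max_indel) window[1] <- as.integer(max_indel)
  if (window[2] <= window[1]) stop("analysis window is empty")
  bases <- (cut_base + window[1]):(cut_base + window[2])
  if (max(bases) > sample$n_bases) stop("window exceeds the sample trace")
  if (max(bases) + max_indel > control$n_bases) stop("window exceeds the control trace")
  if (substr(sample$basecalls, 1, max(1L, cut_base - 5L)) !=
      substr(control$basecalls, 1, max(1L, cut_base - 5L))) {
    warning("sample and control base calls disagree upstream of the cut")
  }

  rows_for_base <- function(b) ((b - 1L) * spacing + 1L):(b * spacing)
  extract <- function(trace, base_idx) {
    as.numeric(trace$intensities[unlist(lapply(base_idx, rows_for_base)), , drop = FALSE])
  }
  y <- extract(sample, bases)
  if (stats::sd(extract(control, bases)) == 0) stop("degenerate control trace (zero variance)")

  shifts <- seq.int(-max_indel, max_indel)
  C <- matrix(0, length(y), length(shifts))
  for (si in seq_along(shifts)) {
    k <- shifts[si]
    src <- bases - k # control base providing the signal at each sample base
    M <- matrix(0.25, length(bases) * spacing, 4L) # unknown inserted base: flat
    known <- which(!(k > 0 & bases <= cut_base + k))
    if (length(known)) {
      rows_dst <- unlist(lapply(known, function(j) ((j - 1L) * spacing + 1L):(j * spacing)))
      rows_src <- unlist(lapply(src[known], rows_for_base))
      M[rows_dst, ] <- control$intensities[rows_src, , drop = FALSE]
    }
    C[, si] <- as.numeric(M)
  }
  fit <- pracma::lsqnonneg(C, y)
  w <- fit$x
  names(w) <- shifts
  fitted <- as.numeric(C %*% w)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else max(0, 1 - ss_res / ss_tot)
  total <- sum(w)
  freq <- if (total > 0) w / total else w
  structure(
    list(
      frequencies = freq, raw_weights = w, r_squared = r2,
      window = window, low_fit = r2 < 0.9
    ),
    class = "decomposition"
  )
}

#' @export
print.decomposition <- function(x, ...) {
  nz <- x$frequencies[x$frequencies > 1e-4]
  cat("<decomposition> R^2 =", sprintf("%.3f", x$r_squared),
      if (x$low_fit) "(low fit)" else "", "\n")
  for (k in names(nz)) cat(" ", k, ":", sprintf("%.3f", nz[[k]]), "\n")
  invisible(x)
}
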