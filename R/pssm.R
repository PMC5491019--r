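## Position-specific scoring matrix support.
##
## A profile is a (2n+1) x 20 matrix of per-offset scores, rows aligned to
## window offsets -n..+n and columns the 20 standard amino acids. Profiles
## either come from an external PSI-BLAST ASCII file or are approximated
## internally as log2 odds of the training-fragment residue frequencies
## against a uniform background.

new_pssm_profile <- function(scores, n) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L) stop("a PSSM profile needs 20 score columns")
  if (nrow(scores) != 2L * n + 1L) {
    stop("profile has ", nrow(scores), " rows; expected 2n+1 = ", 2L * n + 1L)
  }
  dimnames(scores) <- list(window_offsets(n), AA_STANDARD)
  structure(scores, n = as.integer(n),
            class = c("pssm_profile", class(scores)))
}

#' Build an internal PSSM profile from fragments
#'
#' Desk-scale stand-in for a PSI-BLAST profile: per window offset, the
#' log2 odds of the observed residue frequency (over non-`'X'` residues)
#' against a uniform 1/20 background, with a symmetric pseudocount.
#' A residue-uniform fragment set therefore scores 0 everywhere.
#'
#' @inheritParams encode_binary
#' @param pseudocount Additive smoothing applied to both the observed
#'   frequency and the background (default 0.05).
#' @return A `(2n+1) x 20` matrix of class `"pssm_profile"`.
#' @export
build_internal_pssm <- function(fragments, pseudocount = 0.05) {
  frags <- as_fragment_strings(fragments)
  if (length(frags) == 0L) stop("cannot build a PSSM from zero fragments")
  mat <- fragment_char_matrix(frags)
  L <- ncol(mat)
  scores <- t(vapply(seq_len(L), function(j) {
    cnt <- tabulate(match(mat[, j], AA_STANDARD), nbins = 20L)
    tot <- sum(cnt)
    freq <- if (tot > 0) cnt / tot else rep(0, 20L)
    log2((freq + pseudocount) / (1 / 20 + pseudocount))
  }, numeric(20L)))
  new_pssm_profile(scores, (L - 1L) %/% 2L)
}

#' Read a PSI-BLAST ASCII PSSM profile
#'
#' Parses the first 20 score columns of the standard ASCII PSSM dialect
#' (a header line naming the 20 amino-acid columns followed by one row per
#' sequence position: index, residue, 20 integer scores). Scores are
#' reordered to alphabetical amino-acid order.
#'
#' @param path Path to the ASCII PSSM file.
#' @param center Optional 1-based sequence position to window on.
#' @param n Window half-width; required with `center`, otherwise the file
#'   must contain exactly `2n+1` rows (with `n` inferred when `NULL`).
#' @return A `"pssm_profile"`.
#' @export
load_pssm <- function(path, center = NULL, n = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path)
  toks <- lapply(strsplit(trimws(lines), "\\s+"), function(x) x[nzchar(x)])
  hdr <- which(vapply(toks, function(x) {
    length(x) >= 20L && all(x[1:20] %in% AA_STANDARD) &&
      !anyDuplicated(x[1:20])
  }, logical(1)))[1]
  if (is.na(hdr)) stop("malformed PSSM: no amino-acid header line found")
  col_aa <- toks[[hdr]][1:20]
  rows <- list(); res <- character()
  for (i in seq(hdr + 1L, length(toks))) {
    x <- toks[[i]]
    if (length(x) < 22L || is.na(suppressWarnings(as.integer(x[1])))) break
    sc <- suppressWarnings(as.numeric(x[3:22]))
    if (anyNA(sc)) stop("malformed PSSM score row: ", lines[i])
    res <- c(res, x[2]); rows[[length(rows) + 1L]] <- sc
  }
  if (!length(rows)) stop("malformed PSSM: no score rows")
  scores <- do.call(rbind, rows)[, match(AA_STANDARD, col_aa), drop = FALSE]
  if (!is.null(center)) {
    if (is.null(n)) stop("'n' is required when windowing on 'center'")
    idx <- center + window_offsets(n)
    win <- matrix(0, nrow = length(idx), ncol = 20L)
    ok <- idx >= 1L & idx <= nrow(scores)
    win[ok, ] <- scores[idx[ok], , drop = FALSE]
    scores <- win
  } else if (is.null(n)) {
    if (nrow(scores) %% 2L != 1L) stop("profile row count is not 2n+1")
    n <- (nrow(scores) - 1L) %/% 2L
  }
  new_pssm_profile(scores, n)
}

#' Write a profile in the PSI-BLAST ASCII dialect
#'
#' Produces a file that [load_pssm()] round-trips. Residue letters in
#' column 2 are taken from `residues` (default `'C'` at offset 0, `'X'`
#' elsewhere, matching a window profile).
#'
#' @param profile A `"pssm_profile"`.
#' @param path Output path.
#' @param residues Optional character vector of row residues.
#' @export
write_pssm <- function(profile, path, residues = NULL) {
  n <- attr(profile, "n")
  if (is.null(residues)) {
    residues <- rep("X", 2L * n + 1L)
    residues[n + 1L] <- "C"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste0("    ", paste(sprintf("%3s", AA_STANDARD), collapse = ""))),
             con)
  for (i in seq_len(nrow(profile))) {
    writeLines(sprintf("%4d %s %s", i, residues[i],
                       paste(sprintf("%6.2f", profile[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' PSSM encoding with residue-type aggregation and logistic normalization
#'
#' The `(2n+1) x 20` window profile is collapsed to a 20 x 20 matrix by
#' summing rows whose fragment residue is the same amino-acid type (`'X'`
#' rows are discarded; types absent from the fragment keep zero rows).
#' Every element is divided by the window length and squashed through the
#' logistic function `1 / (1 + exp(-x))`, then flattened row-major with
#' rows in alphabetical amino-acid order (400 values).
#'
#' @inheritParams encode_binary
#' @param profile A `"pssm_profile"` aligned to the fragment window.
#' @return Matrix with 400 columns, elements in (0, 1).
#' @export
encode_pssm <- function(fragments, profile) {
  frags <- as_fragment_strings(fragments)
  mat <- fragment_char_matrix(frags)
  L <- ncol(mat)
  if (nrow(profile) != L) stop("profile window does not match fragments")
  out <- matrix(0, nrow = length(frags), ncol = 400L)
  for (j in seq_len(L)) {
    bin <- match(mat[, j], AA_STANDARD)
    for (b in unique(bin[!is.na(bin)])) {
      cols <- (b - 1L) * 20L + seq_len(20L)
      sel <- which(bin == b)
      out[sel, cols] <- out[sel, cols] +
        matrix(profile[j, ], nrow = length(sel), ncol = 20L, byrow = TRUE)
    }
  }
  out <- 1 / (1 + exp(-out / L))
  colnames(out) <- paste0("pssm.", rep(AA_STANDARD, each = 20L), ".", AA_STANDARD)
  out
}
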