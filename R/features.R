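## Numeric feature encodings of window fragments.
##
## All encoders are deterministic and accept either a `palm_fragments`
## dataset or a character vector of equal-length fragments; they return one
## row per fragment. Conventions for the padding symbol 'X': all-zero
## blocks in the orthogonal binary and BLOSUM62 encodings, a 21st counted
## symbol in the composition and position-weight encodings, and discarded
## rows in the PSSM transform.

as_fragment_strings <- function(x) {
  if (inherits(x, "palm_fragments")) x$fragment else as.character(x)
}

## Feature scheme registry: canonical concatenation order for hybrids
## (composition features first, then positional encodings).
FEATURE_SCHEMES <- c("aac", "aapc", "binary", "blosum62", "pwm", "pssm", "asa")

feature_dim <- function(scheme, n) {
  L <- 2L * n + 1L
  switch(scheme,
         aac = 21L, aapc = 441L, binary = L * 20L, blosum62 = L * 20L,
         pwm = L, pssm = 400L, asa = L,
         stop("unknown feature scheme: ", scheme))
}

#' Orthogonal binary (one-hot) encoding
#'
#' Each window position contributes a 20-element indicator over the
#' standard amino acids; `'X'` positions encode as all zeros.
#'
#' @param fragments A `palm_fragments` dataset or character vector.
#' @return Numeric matrix, one row per fragment, `(2n+1) * 20` columns.
#' @export
encode_binary <- function(fragments) {
  frags <- as_fragment_strings(fragments)
  mat <- fragment_char_matrix(frags)
  L <- ncol(mat)
  out <- matrix(0, nrow = length(frags), ncol = L * 20L)
  idx <- match(mat, AA_STANDARD)           # column-major over positions
  pos <- arrayInd(seq_along(idx), dim(mat))
  ok <- !is.na(idx)
  out[cbind(pos[ok, 1L], (pos[ok, 2L] - 1L) * 20L + idx[ok])] <- 1
  colnames(out) <- paste0("bin.", rep(window_offsets((L - 1L) %/% 2L),
                                      each = 20L), ".", AA_STANDARD)
  out
}

#' Amino acid composition (AAC)
#'
#' Relative frequency of the 21 symbols (20 amino acids + `'X'`) within
#' the window; rows sum to 1.
#'
#' @inheritParams encode_binary
#' @return Matrix with 21 columns.
#' @export
encode_aac <- function(fragments) {
  frags <- as_fragment_strings(fragments)
  mat <- fragment_char_matrix(frags)
  idx <- matrix(match(mat, AA_ALPHABET), nrow = nrow(mat))
  out <- t(apply(idx, 1L, tabulate, nbins = 21L)) / ncol(mat)
  colnames(out) <- paste0("aac.", AA_ALPHABET)
  out
}

#' Amino acid pair composition (AAPC)
#'
#' Relative frequency of ordered adjacent residue pairs over the `2n`
#' dipeptide windows; 441 = 21 x 21 columns summing to 1 per row.
#'
#' @inheritParams encode_binary
#' @return Matrix with 441 columns.
#' @export
encode_aapc <- function(fragments) {
  frags <- as_fragment_strings(fragments)
  mat <- fragment_char_matrix(frags)
  L <- ncol(mat)
  idx <- matrix(match(mat, AA_ALPHABET), nrow = nrow(mat))
  left <- idx[, -L, drop = FALSE]
  right <- idx[, -1L, drop = FALSE]
  pair <- (left - 1L) * 21L + right
  out <- t(apply(pair, 1L, tabulate, nbins = 441L)) / (L - 1L)
  colnames(out) <- paste0("aapc.", rep(AA_ALPHABET, each = 21L), AA_ALPHABET)
  out
}

## BLOSUM62 over the 20 standard amino acids, alphabetical order.
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA_STANDARD, AA_STANDARD]
    }
    cache
  }
})

#' BLOSUM62 substitution-score encoding
#'
#' Each window position contributes the 20 BLOSUM62 substitution scores of
#' the observed residue; `'X'` positions contribute zeros.
#'
#' @inheritParams encode_binary
#' @return Matrix with `(2n+1) * 20` columns.
#' @export
encode_blosum62 <- function(fragments) {
  frags <- as_fragment_strings(fragments)
  mat <- fragment_char_matrix(frags)
  L <- ncol(mat)
  B <- blosum62_matrix()
  out <- matrix(0, nrow = length(frags), ncol = L * 20L)
  for (j in seq_len(L)) {
    idx <- match(mat[, j], AA_STANDARD)
    ok <- !is.na(idx)
    out[ok, (j - 1L) * 20L + seq_len(20L)] <- B[idx[ok], , drop = FALSE]
  }
  colnames(out) <- paste0("b62.", rep(window_offsets((L - 1L) %/% 2L),
                                      each = 20L), ".", AA_STANDARD)
  out
}

#' Build a position weight matrix from positive fragments
#'
#' Entry (symbol, offset) is the relative frequency of the symbol among
#' the fragments at that window offset; columns sum to 1 over the 21
#' symbols (20 amino acids + `'X'`).
#'
#' @inheritParams encode_binary
#' @return 21 x (2n+1) matrix of class `"palm_pwm"`; columns are labelled
#'   by window offset -n..+n.
#' @export
build_pwm <- function(fragments) {
  frags <- as_fragment_strings(fragments)
  if (length(frags) == 0L) stop("cannot build a PWM from zero fragments")
  mat <- fragment_char_matrix(frags)
  L <- ncol(mat)
  pwm <- vapply(seq_len(L), function(j) {
    tabulate(match(mat[, j], AA_ALPHABET), nbins = 21L) / nrow(mat)
  }, numeric(21L))
  dimnames(pwm) <- list(AA_ALPHABET, window_offsets((L - 1L) %/% 2L))
  class(pwm) <- c("palm_pwm", class(pwm))
  pwm
}

#' Position frequency matrix of a fragment set
#'
#' Alias of [build_pwm()]; exported under the name used for motif
#' composition reporting (logo-style matrix export).
#'
#' @inheritParams encode_binary
#' @export
position_frequency_matrix <- function(fragments) build_pwm(fragments)

#' Write a PWM / position frequency matrix as TSV
#'
#' @param pwm Matrix from [build_pwm()].
#' @param path Output path.
#' @export
write_pwm <- function(pwm, path) {
  df <- data.frame(symbol = rownames(pwm), unclass(pwm), check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Position-weight-matrix encoding
#'
#' Per-position lookup: element at window offset `o` is the PWM frequency
#' of the observed residue at `o`.
#'
#' @inheritParams encode_binary
#' @param pwm Matrix from [build_pwm()] with matching window.
#' @return Matrix with `2n+1` columns, values in \[0, 1\].
#' @export
encode_pwm <- function(fragments, pwm) {
  frags <- as_fragment_strings(fragments)
  mat <- fragment_char_matrix(frags)
  if (ncol(mat) != ncol(pwm)) stop("PWM window does not match fragments")
  out <- vapply(seq_len(ncol(mat)), function(j) {
    pwm[cbind(match(mat[, j], rownames(pwm)), j)]
  }, numeric(nrow(mat)))
  out <- matrix(out, nrow = nrow(mat))
  colnames(out) <- paste0("pwm.", colnames(pwm))
  out
}

#' Accessible-surface-area encoding
#'
#' Looks up per-residue ASA percentages for every window position and
#' rescales to \[0, 1\] (`percent / 100`, clipped). Padding positions and
#' residues missing from the table encode as 0.
#'
#' @param dataset A `palm_fragments` dataset (protein ids and positions are
#'   needed for the lookup).
#' @param asa_table data.frame with columns `protein_id`, `position`,
#'   `asa` (percent solvent accessibility).
#' @return Matrix with `2n+1` columns.
#' @export
encode_asa <- function(dataset, asa_table) {
  stopifnot(inherits(dataset, "palm_fragments"))
  need <- c("protein_id", "position", "asa")
  if (!all(need %in% names(asa_table))) {
    stop("asa_table must have columns: ", paste(need, collapse = ", "))
  }
  n <- attr(dataset, "n")
  offs <- window_offsets(n)
  key <- paste(asa_table$protein_id, asa_table$position)
  val <- pmin(pmax(asa_table$asa / 100, 0), 1)
  out <- vapply(offs, function(o) {
    v <- val[match(paste(dataset$protein_id, dataset$position + o), key)]
    v[is.na(v)] <- 0
    v
  }, numeric(nrow(dataset)))
  out <- matrix(out, nrow = nrow(dataset))
  colnames(out) <- paste0("asa.", offs)
  out
}

#' Read an ASA table from TSV
#'
#' Columns: `protein_id<TAB>position<TAB>asa` (headerless or headered).
#'
#' @param path Path to the TSV file.
#' @export
read_asa_table <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (identical(tolower(raw[[1]][1]), "protein_id")) raw <- raw[-1, , drop = FALSE]
  data.frame(protein_id = as.character(raw[[1]]),
             position = as.integer(raw[[2]]),
             asa = as.numeric(raw[[3]]), stringsAsFactors = FALSE)
}

#' Encode fragments under a (possibly hybrid) feature recipe
#'
#' Requested schemes are concatenated in the fixed registry order
#' `aac, aapc, binary, blosum62, pwm, pssm, asa`, so a hybrid such as
#' AAC + PSSM always has its 21 composition columns first.
#'
#' @param dataset A `palm_fragments` dataset (or character vector when no
#'   scheme requires protein coordinates).
#' @param recipe Character vector of scheme names.
#' @param context List of fitted helpers: `pwm` (for `"pwm"`), `pssm`
#'   (a profile, for `"pssm"`), `asa_table` (for `"asa"`).
#' @return Numeric feature matrix, one row per fragment.
#' @export
encode_features <- function(dataset, recipe = c("aac", "pssm"),
                            context = list()) {
  recipe <- match.arg(recipe, FEATURE_SCHEMES, several.ok = TRUE)
  recipe <- FEATURE_SCHEMES[FEATURE_SCHEMES %in% recipe]
  blocks <- lapply(recipe, function(s) {
    switch(s,
           aac = encode_aac(dataset),
           aapc = encode_aapc(dataset),
           binary = encode_binary(dataset),
           blosum62 = encode_blosum62(dataset),
           pwm = {
             if (is.null(context$pwm)) stop("recipe 'pwm' needs context$pwm")
             encode_pwm(dataset, context$pwm)
           },
           pssm = {
             if (is.null(context$pssm)) stop("recipe 'pssm' needs context$pssm")
             encode_pssm(dataset, context$pssm)
           },
           asa = {
             if (is.null(context$asa_table)) stop("recipe 'asa' needs context$asa_table")
             encode_asa(dataset, context$asa_table)
           })
  })
  do.call(cbind, blocks)
}

#' Fit a min-max feature scaler
#'
#' Records the per-column minimum and maximum of the training matrix; the
#' transform maps train minimum to -1 and maximum to +1. Constant columns
#' map to 0, and unseen values are clipped into \[-1, +1\].
#'
#' @param x Training feature matrix.
#' @return Object of class `"palm_scaler"`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("cannot fit a scaler on an empty matrix")
  structure(list(min = apply(x, 2L, min), max = apply(x, 2L, max)),
            class = "palm_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `"palm_scaler"`.
#' @export
apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$min)) stop("scaler dimension mismatch")
  rng <- scaler$max - scaler$min
  const <- rng == 0
  rng[const] <- 1
  out <- sweep(sweep(x, 2L, scaler$min), 2L, rng, "/") * 2 - 1
  out[, const] <- 0
  pmin(pmax(out, -1), 1)
}
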