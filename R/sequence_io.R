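## Sequence and site input, window-fragment extraction, homology reduction.
##
## Coordinates are 1-based everywhere; window offsets run -n..+n with 0 at
## the candidate cysteine. Residues outside the 20 standard letters are
## mapped to 'X', which is also the terminal padding symbol.

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and any character outside the 20 standard
#' amino-acid letters (e.g. B, Z, J, U, O, *) is mapped to `'X'`.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header. Class `"palm_proteins"`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- clean_sequences(as.character(set))
  names(seqs) <- ids
  class(seqs) <- c("palm_proteins", class(seqs))
  seqs
}

## Uppercase and map non-standard residue letters to 'X'.
clean_sequences <- function(seqs) {
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0L)) stop("empty sequence encountered")
  gsub(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")), "X", seqs)
}

#' Read site annotations from a TSV file
#'
#' Expected headerless columns: `protein_id<TAB>position[<TAB>label]`.
#' The label defaults to `"positive"`. A header line whose first field is
#' `protein_id` is tolerated and skipped.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `protein_id`, `position`, `label`.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("site file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (identical(tolower(raw[[1]][1]), "protein_id")) raw <- raw[-1, , drop = FALSE]
  if (ncol(raw) < 2L) stop("site TSV needs at least 2 columns")
  lab <- if (ncol(raw) >= 3L) as.character(raw[[3]]) else rep("", nrow(raw))
  lab[is.na(lab) | lab == ""] <- "positive"
  out <- data.frame(protein_id = as.character(raw[[1]]),
                    position   = as.integer(raw[[2]]),
                    label      = lab,
                    stringsAsFactors = FALSE)
  if (anyNA(out$position)) stop("non-numeric site position in ", path)
  bad <- setdiff(unique(out$label), c("positive", "negative"))
  if (length(bad)) stop("unknown site label(s): ", paste(bad, collapse = ", "))
  out
}

#' Extract a cysteine-centered window fragment
#'
#' Returns the `2n + 1`-mer `sequence[position - n .. position + n]`, with
#' positions falling outside the sequence filled by `'X'`.
#'
#' @param sequence Single protein sequence (character scalar).
#' @param position 1-based residue index of the site.
#' @param n Window half-width (window length is `2n + 1`).
#' @param strict_center If `TRUE` (default), require the centered residue
#'   to be a cysteine.
#' @return Fragment string of length `2n + 1`.
#' @export
extract_fragment <- function(sequence, position, n = 10L, strict_center = TRUE) {
  stopifnot(length(sequence) == 1L, n >= 0L)
  len <- nchar(sequence)
  if (any(position < 1L | position > len)) {
    stop("position out of range 1..", len)
  }
  centers <- substring(sequence, position, position)
  if (strict_center && any(centers != "C")) {
    stop("center residue is not 'C' at position ",
         paste(position[centers != "C"], collapse = ", "))
  }
  padded <- paste0(strrep("X", n), sequence, strrep("X", n))
  substring(padded, position, position + 2L * n)
}

#' Construct a fragment dataset
#'
#' Low-level constructor validating the fragment-collection invariants:
#' uniform window length `2n + 1`, alphabet restricted to the 20 standard
#' amino acids plus `'X'`, unique (protein, position) keys, and (in strict
#' mode) a cysteine at the center.
#'
#' @param protein_id,position,fragment,label Parallel vectors.
#' @param n Window half-width.
#' @param strict_center Require `'C'` at offset 0.
#' @return data.frame of class `"palm_fragments"` with attribute `n`.
#' @export
fragment_dataset <- function(protein_id, position, fragment, label,
                             n, strict_center = TRUE) {
  df <- data.frame(protein_id = as.character(protein_id),
                   position = as.integer(position),
                   fragment = as.character(fragment),
                   label = as.character(label),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(nchar(df$fragment) != 2L * n + 1L)) {
      stop("all fragments must have length 2n+1 = ", 2L * n + 1L)
    }
    if (any(grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                  df$fragment))) {
      stop("fragment contains characters outside the amino-acid alphabet + X")
    }
    if (strict_center &&
        any(substring(df$fragment, n + 1L, n + 1L) != "C")) {
      stop("fragment center must be 'C' in strict mode")
    }
    key <- paste(df$protein_id, df$position)
    if (anyDuplicated(key)) {
      stop("duplicate (protein_id, position) in fragment dataset")
    }
    if (!all(df$label %in% c("positive", "negative"))) {
      stop("labels must be 'positive' or 'negative'")
    }
  }
  attr(df, "n") <- as.integer(n)
  class(df) <- c("palm_fragments", "data.frame")
  df
}

#' @export
print.palm_fragments <- function(x, ...) {
  n <- attr(x, "n")
  cat(sprintf("<palm_fragments> %d fragments (window %d, n = %d): %d positive, %d negative\n",
              nrow(x), 2L * n + 1L, n,
              sum(x$label == "positive"), sum(x$label == "negative")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Build a labelled fragment dataset from proteins and site annotations
#'
#' One positive fragment is extracted per annotated site; every other
#' cysteine of each annotated protein yields a negative fragment.
#'
#' @param proteins Named character vector of sequences (see [read_fasta()]).
#' @param sites data.frame as returned by [read_sites()]; rows labelled
#'   `"positive"` define the positive sites.
#' @param n Window half-width (default 10, i.e. 21-mers).
#' @param strict_center Require annotated residues to be cysteine.
#' @return A `"palm_fragments"` dataset.
#' @export
build_dataset <- function(proteins, sites, n = 10L, strict_center = TRUE) {
  unknown <- setdiff(unique(sites$protein_id), names(proteins))
  if (length(unknown)) {
    stop("annotation references unknown protein(s): ",
         paste(unknown, collapse = ", "))
  }
  pos_sites <- sites[sites$label == "positive", , drop = FALSE]
  rows <- lapply(unique(sites$protein_id), function(pid) {
    seq <- proteins[[pid]]
    cys <- which(strsplit(seq, "", fixed = TRUE)[[1]] == "C")
    ppos <- pos_sites$position[pos_sites$protein_id == pid]
    if (strict_center && !all(ppos %in% cys)) {
      stop("positive annotation on non-cysteine residue in ", pid)
    }
    all_pos <- sort(unique(c(cys, if (!strict_center) ppos)))
    lab <- ifelse(all_pos %in% ppos, "positive", "negative")
    data.frame(protein_id = pid, position = all_pos, label = lab,
               fragment = extract_fragment(seq, all_pos, n,
                                           strict_center = strict_center),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(protein_id = character(), position = integer(),
                                    label = character(), fragment = character())
  fragment_dataset(df$protein_id, df$position, df$fragment, df$label, n,
                   strict_center = strict_center)
}

## Fractional identity between one fragment (character vector) and each row
## of a character matrix; 'X' matches only 'X' under plain equality.
fragment_identity <- function(chars, mat) {
  rowMeans(mat == matrix(chars, nrow = nrow(mat), ncol = length(chars),
                         byrow = TRUE))
}

#' Remove homologous and cross-labelled duplicate fragments
#'
#' Two-step homology reduction emulating the CD-HIT protocol at fragment
#' level: (a) any negative fragment whose sequence is identical to a
#' positive fragment is discarded (the positive is kept); (b) within each
#' label class, fragments are sorted by descending length then
#' lexicographically and greedily clustered against the retained
#' representatives at the given identity threshold (identity = matching
#' positions / window length; `'X'` matches only `'X'`), keeping the first
#' representative encountered. Deterministic given the input.
#'
#' @param dataset A `"palm_fragments"` dataset.
#' @param identity_threshold Fraction in (0, 1]; fragments with identity
#'   `>=` the threshold to a retained representative are dropped
#'   (at threshold 1 only exact duplicates are removed).
#' @return The reduced dataset, rows in original input order.
#' @export
deduplicate <- function(dataset, identity_threshold = 0.5) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (nrow(dataset) == 0L) return(dataset)
  n <- attr(dataset, "n")
  pos_frag <- dataset$fragment[dataset$label == "positive"]
  drop_cross <- dataset$label == "negative" & dataset$fragment %in% pos_frag
  keep <- !drop_cross

  for (lab in c("positive", "negative")) {
    idx <- which(keep & dataset$label == lab)
    if (length(idx) < 2L) next
    ## CD-HIT-like processing order: longest first (all equal here), then
    ## lexicographic; ties broken by input order via stable sort.
    ord <- idx[order(-nchar(dataset$fragment[idx]), dataset$fragment[idx])]
    mat <- fragment_char_matrix(dataset$fragment[ord])
    kept_rows <- 1L
    for (i in seq_along(ord)[-1L]) {
      ident <- fragment_identity(mat[i, ], mat[kept_rows, , drop = FALSE])
      if (identity_threshold < 1) {
        redundant <- any(ident >= identity_threshold)
      } else {
        redundant <- any(ident >= 1)
      }
      if (redundant) keep[ord[i]] <- FALSE else kept_rows <- c(kept_rows, i)
    }
  }
  out <- dataset[keep, , drop = FALSE]
  attr(out, "n") <- n
  class(out) <- c("palm_fragments", "data.frame")
  rownames(out) <- NULL
  out
}

#' Write / read a fragment dataset as TSV
#'
#' Columns: `protein_id<TAB>position<TAB>fragment<TAB>label`.
#'
#' @param dataset A `"palm_fragments"` dataset.
#' @param path Output path.
#' @export
write_fragments <- function(dataset, path) {
  write_tsv(as.data.frame(dataset)[, c("protein_id", "position",
                                       "fragment", "label")], path)
  invisible(path)
}

#' @rdname write_fragments
#' @param strict_center Passed to [fragment_dataset()].
#' @export
read_fragments <- function(path, strict_center = TRUE) {
  df <- read_tsv(path)
  need <- c("protein_id", "position", "fragment", "label")
  if (!all(need %in% names(df))) {
    stop("fragment TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("fragment TSV is empty: ", path)
  w <- unique(nchar(df$fragment))
  if (length(w) != 1L || w %% 2L != 1L) {
    stop("fragments must share one odd window length")
  }
  fragment_dataset(df$protein_id, df$position, df$fragment, df$label,
                   n = (w - 1L) %/% 2L, strict_center = strict_center)
}
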