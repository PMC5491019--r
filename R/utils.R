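#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded package internals do not perturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

## Derive a distinct sub-seed from a base seed, kept within 32-bit range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1103L + 7919L * k) %% 2147483629)
}

## Fragment strings -> character matrix (one row per fragment).
fragment_char_matrix <- function(fragments) {
  stopifnot(is.character(fragments))
  if (length(fragments) == 0L) {
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  widths <- unique(nchar(fragments))
  if (length(widths) != 1L) {
    stop("fragments must all have the same length")
  }
  matrix(unlist(strsplit(fragments, "", fixed = TRUE), use.names = FALSE),
         nrow = length(fragments), ncol = widths, byrow = TRUE)
}

## Offset labels -n..+n for a window of half-width n (0 at the site).
window_offsets <- function(n) seq.int(-n, n)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
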