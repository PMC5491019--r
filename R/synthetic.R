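## Seeded generator of cysteine-centered fragment datasets with planted
## property-group motifs. The generator states a simple world: negatives
## are i.i.d. background residues with the center forced to 'C';
## positives additionally carry one motif rule-set (chosen by mixture
## weight), each rule overwriting its offset with a uniform draw from the
## rule's residue set with the stated probability.

#' A planted motif rule
#'
#' @param offset Window offset in `-n..+n`, nonzero.
#' @param group A property-group name from [aa_group_scheme()] (resolved
#'   to its residue set), or `NULL` when `residues` is given.
#' @param residues Explicit residue set overriding `group`.
#' @param prob Probability that a positive fragment carries the rule.
#' @param scheme Scheme used to resolve `group`.
#' @return List of class `"motif_rule"`.
#' @export
motif_rule <- function(offset, group = NULL, residues = NULL, prob = 0.85,
                       scheme = aa_group_scheme()) {
  stopifnot(offset != 0L, prob > 0, prob <= 1)
  if (is.null(residues)) {
    if (is.null(group) || !group %in% MDD_GROUPS) {
      stop("give either a valid property group or an explicit residue set")
    }
    residues <- names(scheme)[scheme == group]
  }
  stopifnot(all(residues %in% AA_STANDARD))
  structure(list(offset = as.integer(offset), group = group,
                 residues = residues, prob = prob),
            class = "motif_rule")
}

#' Synthetic dataset configuration
#'
#' @param n Window half-width (default 10).
#' @param n_pos,n_neg Fragment counts per class.
#' @param background Named composition over the 20 standard amino acids
#'   (default uniform); need not be normalized, must be normalizable.
#' @param rules List of rule-sets, each a list with elements `rules` (a
#'   list of [motif_rule()]s) and `weight`; weights must sum to 1. Each
#'   positive fragment is assigned one rule-set by weight.
#' @param seed Integer seed.
#' @return List of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n = 10L, n_pos = 600L, n_neg = 4800L,
                             background = NULL, rules = list(), seed = 1L) {
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20L), AA_STANDARD)
  }
  if (!setequal(names(background), AA_STANDARD)) {
    stop("background must be named by the 20 standard amino acids")
  }
  background <- background[AA_STANDARD]
  if (any(background < 0) || sum(background) <= 0) {
    stop("background composition is not normalizable")
  }
  background <- background / sum(background)
  if (length(rules)) {
    w <- vapply(rules, function(r) r$weight, numeric(1))
    if (abs(sum(w) - 1) > 1e-8) stop("rule-set weights must sum to 1")
    lapply(rules, function(r) {
      lapply(r$rules, function(ru) {
        if (!inherits(ru, "motif_rule")) stop("rules must be motif_rule objects")
        if (abs(ru$offset) > n) stop("rule offset outside the window")
      })
    })
  }
  stopifnot(n_pos >= 0L, n_neg >= 0L)
  structure(list(n = as.integer(n), n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg), background = background,
                 rules = rules, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default synthetic palmitoylation world
#'
#' Four equally weighted single-rule motif rule-sets mirroring the
#' canonical substrate-motif offsets - basic residues at +10 and at +4,
#' polar residues at -1 and at +1 - each carried with probability 0.85,
#' over a uniform background, 600 positives and 4800 negatives (1:8).
#'
#' @param seed Integer seed.
#' @return A [synthetic_config()].
#' @export
default_palm_config <- function(seed = 1L) {
  mk <- function(offset, group) {
    list(rules = list(motif_rule(offset, group, prob = 0.85)), weight = 0.25)
  }
  synthetic_config(n = 10L, n_pos = 600L, n_neg = 4800L,
                   rules = list(mk(10L, "basic"), mk(4L, "basic"),
                                mk(-1L, "polar"), mk(1L, "polar")),
                   seed = seed)
}

#' Generate a synthetic fragment dataset
#'
#' @param config A [synthetic_config()].
#' @return A labelled `"palm_fragments"` dataset (positives first);
#'   deterministic given `config$seed`.
#' @export
generate_fragments <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n
  L <- 2L * n + 1L
  with_seed(config$seed, {
    draw <- function(count) {
      m <- matrix(sample(AA_STANDARD, count * L, replace = TRUE,
                         prob = config$background),
                  nrow = count, ncol = L)
      m[, n + 1L] <- "C"
      m
    }
    pos <- draw(config$n_pos)
    if (config$n_pos > 0L && length(config$rules)) {
      w <- vapply(config$rules, function(r) r$weight, numeric(1))
      assigned <- sample.int(length(config$rules), config$n_pos,
                             replace = TRUE, prob = w)
      for (i in seq_len(config$n_pos)) {
        for (rule in config$rules[[assigned[i]]]$rules) {
          if (stats::runif(1) < rule$prob) {
            pos[i, rule$offset + n + 1L] <-
              sample(rule$residues, 1L)
          }
        }
      }
    }
    neg <- draw(config$n_neg)
    collapse_rows <- function(m) {
      if (nrow(m) == 0L) character(0) else apply(m, 1L, paste, collapse = "")
    }
    frag <- c(collapse_rows(pos), collapse_rows(neg))
    fragment_dataset(
      protein_id = sprintf("synth%05d", seq_len(config$n_pos + config$n_neg)),
      position = rep(n + 1L, config$n_pos + config$n_neg),
      fragment = frag,
      label = rep(c("positive", "negative"), c(config$n_pos, config$n_neg)),
      n = n)
  })
}
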