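# Shared synthetic worlds and tiny file fixtures, built in code.

# A mixture world whose positives carry correlated multi-position motifs,
# so between-position dependence genuinely exists: rule-set A plants basic
# residues at +4/+7/+10 and rule-set B polar residues at -1/+1/+2.
three_rule_config <- function(seed, n_pos = 300L, n_neg = 2400L, prob = 0.95) {
  mk <- function(offs, grp) {
    list(rules = lapply(offs, motif_rule, group = grp, prob = prob),
         weight = 0.5)
  }
  synthetic_config(n = 10L, n_pos = n_pos, n_neg = n_neg,
                   rules = list(mk(c(4L, 7L, 10L), "basic"),
                                mk(c(-1L, 1L, 2L), "polar")),
                   seed = seed)
}

three_rule_planted <- c("4:basic", "7:basic", "10:basic",
                        "-1:polar", "1:polar", "2:polar")

subset_fragments <- function(dataset, rows) {
  out <- dataset[rows, , drop = FALSE]
  attr(out, "n") <- attr(dataset, "n")
  class(out) <- class(dataset)
  out
}

positives_of <- function(dataset) {
  subset_fragments(dataset, which(dataset$label == "positive"))
}

write_tmp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# Random fragment strings (uniform background, 'C' center), plain vector.
random_fragments <- function(k, n = 10L, seed = 1L) {
  generate_fragments(synthetic_config(n = n, n_pos = k, n_neg = 0L,
                                      seed = seed))$fragment
}
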