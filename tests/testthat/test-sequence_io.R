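test_that("read_fasta parses, case-folds and maps non-standard residues", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "mkc", "llv",
               ">p2", "MKBUC"), path)
  prot <- read_fasta(path)
  expect_named(prot, c("p1", "p2"))
  expect_equal(unname(prot["p1"]), "MKCLLV")
  expect_equal(unname(prot["p2"]), "MKXXC")   # B and U map to X

  writeLines(c(">a", "MC", ">a", "MC"), path)
  expect_error(read_fasta(path), "duplicate.*a")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("read_sites handles 2- and 3-column TSVs and bad labels", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("p1\t3", "p2\t7\tnegative"), path)
  sites <- read_sites(path)
  expect_equal(sites$label, c("positive", "negative"))
  expect_equal(sites$position, c(3L, 7L))

  writeLines("p1\t3\tmaybe", path)
  expect_error(read_sites(path), "unknown site label")
})

test_that("extract_fragment pads with X and validates the center", {
  expect_equal(extract_fragment("MKCLLV", 3, n = 10),
               "XXXXXXXXMKCLLVXXXXXXX")
  expect_equal(nchar(extract_fragment("MKCLLV", 3, n = 10)), 21L)
  expect_equal(extract_fragment("C", 1, n = 1), "XCX")
  expect_error(extract_fragment("MKCLLV", 9, n = 2), "out of range")
  expect_error(extract_fragment("MKCLLV", 2, n = 2), "not 'C'")

  # center residue round-trips at every position without strict mode
  seqc <- "AGTCCKYWQPLC"
  for (pos in seq_len(nchar(seqc))) {
    frag <- extract_fragment(seqc, pos, n = 4, strict_center = FALSE)
    expect_equal(substring(frag, 5, 5), substring(seqc, pos, pos))
  }
})

test_that("build_dataset derives negatives from unannotated cysteines", {
  prot <- c(p1 = "ACCA")
  sites <- data.frame(protein_id = "p1", position = 2L, label = "positive")
  ds <- build_dataset(prot, sites, n = 2)
  expect_s3_class(ds, "palm_fragments")
  expect_equal(ds$label[ds$position == 2], "positive")
  expect_equal(ds$label[ds$position == 3], "negative")
  expect_equal(nrow(ds), 2L)

  # protein whose only cysteines are annotated -> zero negatives
  ds2 <- build_dataset(c(q = "ACA"),
                       data.frame(protein_id = "q", position = 2L,
                                  label = "positive"), n = 1)
  expect_equal(sum(ds2$label == "negative"), 0L)

  # disjoint proteins add up, and sites partition the cysteines
  prot3 <- c(a = "CACAC", b = "CCAA")
  sites3 <- data.frame(protein_id = c("a", "b"), position = c(1L, 2L),
                       label = "positive")
  ds3 <- build_dataset(prot3, sites3, n = 1)
  expect_equal(nrow(ds3), 5L)  # all cysteines of both proteins
  cys <- c(paste("a", c(1, 3, 5)), paste("b", c(1, 2)))
  expect_setequal(paste(ds3$protein_id, ds3$position), cys)

  expect_error(build_dataset(prot, data.frame(protein_id = "nope",
                                              position = 1L,
                                              label = "positive"), n = 1),
               "unknown protein")
  expect_error(build_dataset(c(p = "ACA"),
                             data.frame(protein_id = "p", position = 1L,
                                        label = "positive"), n = 1),
               "non-cysteine")
})

test_that("deduplicate removes cross-set duplicates and clusters by identity", {
  n <- 10L
  base <- strrep("A", 10)
  f1 <- paste0(base, "C", base)
  f2 <- paste0(base, "C", strrep("A", 9), "G")       # identity 20/21 to f1
  f3 <- paste0(strrep("G", 8), "AA", "C", base)      # identity 13/21 to f1
  f4 <- paste0(strrep("W", 10), "C", strrep("W", 10))  # far from all

  # cross-set rule: identical negative removed, positive kept
  ds <- fragment_dataset(c("a", "b"), c(11, 11), c(f1, f1),
                         c("positive", "negative"), n)
  out <- deduplicate(ds, 1.0)
  expect_equal(out$label, "positive")

  # threshold 1.0 keeps all-distinct fragments untouched
  ds2 <- fragment_dataset(c("a", "b", "c"), rep(11, 3), c(f1, f2, f4),
                          rep("positive", 3), n)
  expect_equal(nrow(deduplicate(ds2, 1.0)), 3L)

  # hand-computed identities: f1.f2 = 20/21 >= 0.5 clusters; f1.f3 = 13/21
  # also >= 0.5 clusters; f4 survives
  ds3 <- fragment_dataset(c("a", "b", "c"), rep(11, 3), c(f1, f2, f3),
                          rep("positive", 3), n)
  out3 <- deduplicate(ds3, 0.95)
  expect_setequal(out3$fragment, c(f1, f2, f3)[c(1, 3)])  # only f2 folds in

  # idempotence over a larger random set
  big <- generate_fragments(synthetic_config(n = 3, n_pos = 40, n_neg = 40,
                                             seed = 3))
  once <- deduplicate(big, 0.6)
  twice <- deduplicate(once, 0.6)
  expect_equal(as.data.frame(once), as.data.frame(twice))

  # a positive is never removed because of a negative
  ds4 <- fragment_dataset(c("a", "b"), c(11, 11), c(f1, f1),
                          c("negative", "positive"), n)
  out4 <- deduplicate(ds4, 1.0)
  expect_true("positive" %in% out4$label)
  expect_false("negative" %in% out4$label)
})

test_that("fragment TSV export round-trips", {
  ds <- generate_fragments(synthetic_config(n = 5, n_pos = 10, n_neg = 20,
                                            seed = 8))
  path <- tempfile(fileext = ".tsv")
  write_fragments(ds, path)
  back <- read_fragments(path)
  expect_equal(as.data.frame(back), as.data.frame(ds))
  expect_equal(attr(back, "n"), attr(ds, "n"))
})

test_that("fragment_dataset enforces its invariants", {
  expect_error(fragment_dataset("p", 1, "ACA", "positive", n = 2),
               "length 2n\\+1")
  expect_error(fragment_dataset("p", 1, "AZA", "positive", n = 1,
                                strict_center = FALSE),
               "outside the amino-acid alphabet")
  expect_error(fragment_dataset("p", 1, "AAA", "positive", n = 1),
               "center must be 'C'")
  expect_error(fragment_dataset(c("p", "p"), c(1, 1), c("ACA", "GCG"),
                                rep("positive", 2), n = 1),
               "duplicate")
})
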