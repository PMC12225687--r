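test_that("the bundled BLOSUM62 matches the Biostrings reference", {
  B <- blosum62()
  expect_identical(dim(B), c(20L, 20L))
  expect_identical(B, t(B))
  ref <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62[aa_alphabet(), aa_alphabet()]
  })
  storage.mode(ref) <- "integer"
  expect_identical(unname(B), unname(ref))
  # row-wise diagonal dominance
  for (a in aa_alphabet()) {
    expect_true(all(B[a, a] >= B[a, setdiff(aa_alphabet(), a)]))
  }
})

test_that("self-similarities match independent diagonal lookups", {
  B <- blosum62()
  self_sum <- function(s) {
    r <- strsplit(s, "")[[1]]
    sum(diag(B)[match(r, aa_alphabet())])
  }
  expect_identical(self_sum("CASSYVGNTGELFF"), 76L)
  expect_identical(self_sum("SLLMWITQC"), 51L)
  expect_equal(blosum_similarity("CASSYVGNTGELFF"), 76)
  expect_equal(blosum_similarity("CASSVDTNTGELFF"), 53)
})

test_that("identical strings maximize equal-length similarity", {
  set.seed(59)
  ref <- "CASSYVGNTGELFF"
  self <- blosum_similarity(ref)
  others <- replicate(200, paste(
    sample(aa_alphabet(), nchar(ref), replace = TRUE), collapse = ""))
  expect_true(all(blosum_similarity(others, ref) <= self))
})

test_that("unequal lengths are compared by flank-anchored offsets", {
  B <- blosum62()
  ref <- "CASSYVGNTGELFF"
  q <- "CASSNLGSGELFF"       # core NLGS vs YVGNT
  flanks <- sum(diag(B)[match(strsplit("CASSGELFF", "")[[1]],
                              aa_alphabet())])
  a <- strsplit("NLGS", "")[[1]]
  b <- strsplit("YVGNT", "")[[1]]
  offsets <- vapply(0:1, function(o) {
    sum(B[cbind(a, b[(1 + o):(4 + o)])])
  }, numeric(1))
  expected <- flanks + max(offsets) + 1 * min(B)
  expect_equal(blosum_similarity(q, ref), expected)
  expect_error(blosum_similarity("NLGSXX", ref), "flank")
})

test_that("similarity weights apply positionwise", {
  ref <- "CASSYVGNTGELFF"
  w <- rep(0, 14)
  w[5] <- 1   # only the first core position counts
  expect_equal(blosum_similarity(ref, ref, weights = w),
               blosum62()["Y", "Y"])
  expect_error(blosum_similarity(ref, ref, weights = c(1, 2)),
               "one entry per position")
})

test_that("the CDR3 distance behaves like a distance", {
  expect_identical(cdr3_distance("CASSYVGNTGELFF", "CASSYVGNTGELFF"), 0)
  # single substitution Y -> F: BLOSUM62 3 -> cost min(4, 1) * weight 3
  expect_identical(cdr3_distance("CASSYVGNTGELFF", "CASSFVGNTGELFF"), 3)
  # one-residue length difference: one gap at cost 4, weighted
  expect_identical(cdr3_distance("CASSYVGNTGELFF", "CASSYVGNGELFF"),
                   3 * 4)
  set.seed(61)
  rand_cdr3 <- function(n, len = 5L) {
    paste0("CASS", replicate(n, paste(sample(aa_alphabet(), len,
                                             replace = TRUE),
                                      collapse = "")), "GELFF")
  }
  x <- rand_cdr3(50); y <- rand_cdr3(50)
  expect_equal(cdr3_distance(x, y[1]),
               vapply(x, function(a) cdr3_distance(y[1], a), numeric(1),
                      USE.NAMES = FALSE))
  expect_true(all(cdr3_distance(x, y[1])[x != y[1]] > 0))
})

test_that("the triangle inequality holds on random core triples", {
  set.seed(67)
  comp <- default_core_composition()
  seqs <- paste0("CASS", replicate(3000, paste(
    sample(names(comp), 5, replace = TRUE, prob = comp),
    collapse = "")), "GELFF")
  tri <- matrix(seqs, ncol = 3)
  dxy <- cdr3_distance(tri[, 1], tri[, 2])
  dyz <- cdr3_distance(tri[, 2], tri[, 3])
  dxz <- cdr3_distance(tri[, 1], tri[, 3])
  expect_true(all(dxz <= dxy + dyz + 1e-9))
})

test_that("single substitutions are anti-monotone in BLOSUM score", {
  B <- blosum62()
  ref <- "CASSYVGNTGELFF"
  set.seed(71)
  for (i in 1:50) {
    p <- sample(14, 1)
    orig <- substr(ref, p, p)
    repl <- sample(setdiff(aa_alphabet(), orig), 2)
    repl <- repl[order(B[orig, repl], decreasing = TRUE)]
    q1 <- ref; substr(q1, p, p) <- repl[1]   # higher BLOSUM
    q2 <- ref; substr(q2, p, p) <- repl[2]   # lower BLOSUM
    expect_gte(blosum_similarity(q1, ref), blosum_similarity(q2, ref))
    expect_lte(cdr3_distance(q1, ref), cdr3_distance(q2, ref))
  }
})

test_that("exact match is set membership", {
  expect_identical(exact_match_score("CASSNLGGLGELFF",
                                     c("CASSNLGGLGELFF", "X")), 1L)
  expect_identical(exact_match_score("CASSNLGGLGELFF", character()), 0L)
  scr <- tiny_screen(n_input = 500L, n_output = 300L, seed = 73L)
  binders <- scr$truth$cdr3_aa[scr$truth$label == "binder"]
  expect_true(all(exact_match_score(binders,
                                    scr$output_table$cdr3_aa) == 1L))
})

test_that("the benchmark harness scores methods by AUC", {
  labeled <- tibble::tibble(
    cdr3_aa = sprintf("CASS%sGELFF", c("NLGGL", "YVGNT", "AAAAA",
                                       "WWWWW", "GGGGG", "TTTTT")),
    label = c(1, 1, 0, 0, 0, 0)
  )
  oracle <- function(s) labeled$label[match(s, labeled$cdr3_aa)]
  res <- benchmark_methods(labeled, list(
    oracle = oracle,
    anti_oracle = list(score = oracle, type = "distance")
  ))
  expect_equal(res$auc[res$method == "oracle"], 1)
  expect_equal(res$auc[res$method == "anti_oracle"], 0)
  expect_identical(res$n_pos, c(2L, 2L))

  # negating a distance flips the AUC around 0.5
  set.seed(79)
  sc <- stats::rnorm(40)
  lab <- rep(c(1, 0), 20)
  expect_equal(compute_auc(-sc, lab), 1 - compute_auc(sc, lab))

  # a random scorer is at chance on average
  aucs <- replicate(100, {
    compute_auc(stats::rnorm(40), lab)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})
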