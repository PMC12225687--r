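test_that("peptide windows are enumerated with correct counts", {
  prot <- c(P1 = strrep("A", 10L), P2 = strrep("C", 8L),
            P3 = strrep("G", 9L))
  cand <- enumerate_peptides(prot)
  expect_identical(sum(cand$protein == "P1"), 2L)
  expect_identical(sum(cand$protein == "P2"), 0L)
  expect_identical(sum(cand$protein == "P3"), 1L)
  expect_identical(cand$offset[cand$protein == "P3"], 0L)

  set.seed(83)
  prot2 <- synthetic_proteome(n_proteins = 20L,
                              length_range = c(5L, 60L), seed = 7L)
  cand2 <- enumerate_peptides(prot2)
  expect_identical(nrow(cand2),
                   sum(pmax(0L, nchar(prot2) - 8L)))
  expect_error(enumerate_peptides(character()), "empty")
})

test_that("windows with non-standard residues are skipped", {
  prot <- c(P1 = paste0(strrep("A", 9L), "X", strrep("G", 9L)))
  cand <- enumerate_peptides(prot)
  # every window overlapping the X is dropped: 11 windows total, 9 hit X
  expect_identical(nrow(cand), 2L)
  expect_true(all(!grepl("X", cand$peptide)))
  expect_identical(nrow(enumerate_peptides(prot,
                                           nonstandard = "skip_protein")),
                   0L)
})

test_that("FASTA proteomes read back identically to in-memory ones", {
  path <- withr::local_tempfile(fileext = ".fasta")
  prot <- synthetic_proteome(n_proteins = 5L, plant = "FLTLWLTQV",
                             seed = 11L)
  synthetic_proteome(n_proteins = 5L, plant = "FLTLWLTQV", seed = 11L,
                     path = path)
  expect_identical(enumerate_peptides(path), enumerate_peptides(prot))
  expect_true("FLTLWLTQV" %in% enumerate_peptides(prot)$peptide)
})

test_that("the binding-rank filter keeps strictly sub-threshold peptides", {
  cand <- tibble::tibble(peptide = c("SLLMWITQC", "FLTLWLTQV",
                                     "AAAAAAAAA"),
                         protein = "P", offset = 0:2)
  rank_file <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    peptide = c("SLLMWITQC", "FLTLWLTQV"),
    rank = c(0.4, 1.5)), rank_file)
  cfg <- scan_config(rank_source = list(mode = "external",
                                        path = rank_file))
  expect_message(out <- filter_binders(cand, cfg), "dropped 1")
  expect_identical(out$peptide, "SLLMWITQC")   # 1.5 is not below 1.5
  expect_identical(out$binding_rank, 0.4)

  cfg_err <- scan_config(rank_source = list(mode = "external",
                                            path = rank_file),
                         on_missing_rank = "error")
  expect_error(filter_binders(cand, cfg_err), "no %rank")

  none <- filter_binders(cand, scan_config())
  expect_identical(nrow(none), 3L)
  expect_true(all(is.na(none$binding_rank)))
})

test_that("the heuristic anchor filter keeps canonical A2 binders", {
  cand <- tibble::tibble(peptide = c("FLTLWLTQV", "AAAAAAAAA",
                                     "GLRMWIKQV"),
                         protein = "P", offset = 0:2)
  out <- filter_binders(cand, scan_config(rank_source = list(
    mode = "heuristic")))
  expect_setequal(out$peptide, c("FLTLWLTQV", "GLRMWIKQV"))
})

test_that("epitope similarity matches independent lookups", {
  expect_equal(similarity_to_epitope("SLLMWITQC"), 51)
  expect_equal(similarity_to_epitope("FLTLWLTQV"), 25)
  expect_error(similarity_to_epitope("SLLM"), "length")
})

test_that("anchor residues are enforced before ranking", {
  cfg <- scan_config()
  expect_true(anchors_ok("FLTLWLTQV", cfg))
  expect_false(anchors_ok("FLTLALTQV", cfg))   # A at position 5
  cand <- tibble::tibble(
    peptide = c("SLLMWITQC", "FLTLALTQV"),
    protein = "P", offset = c(0L, 1L))
  report <- rank_candidates(cand, cfg = cfg)
  expect_identical(report$peptide, "SLLMWITQC")
  expect_identical(report$position, 1L)   # offsets are reported 1-based
})

test_that("ranked reports are deterministic and anchored peptides win", {
  prot <- synthetic_proteome(n_proteins = 3L,
                             length_range = c(60L, 120L),
                             plant = "FLTLWLTQV", seed = 13L)
  cfg <- scan_config()
  cand <- enumerate_peptides(prot)
  r1 <- rank_candidates(cand, cfg = cfg)
  r2 <- rank_candidates(cand, cfg = cfg)
  expect_identical(r1, r2)
  expect_true("FLTLWLTQV" %in% r1$peptide)
  expect_true(all(anchors_ok(r1$peptide, cfg)))
  # windows lacking W5/Q8 are rejected, so the planted peptide outranks
  # every non-anchored window by construction
  expect_identical(r1$peptide[1],
                   r1$peptide[which.max(r1$similarity)])
  few <- rank_candidates(cand, top_n = 3L, cfg = cfg)
  expect_lte(nrow(few), 3L)
  all_of_them <- rank_candidates(cand, top_n = 1e6, cfg = cfg)
  expect_identical(nrow(all_of_them), nrow(r1))
})

test_that("the epitope maximizes similarity among random peptides", {
  set.seed(89)
  cfg <- scan_config()
  peptides <- replicate(10000, paste(sample(aa_alphabet(), 9,
                                            replace = TRUE),
                                     collapse = ""))
  sims <- similarity_to_epitope(peptides, cfg)
  expect_true(all(sims <= similarity_to_epitope(cfg$epitope, cfg)))
})

test_that("filter composition order does not change the final set", {
  prot <- synthetic_proteome(n_proteins = 10L, plant = "FLTLWLTQV",
                             seed = 17L)
  cfg <- scan_config(rank_source = list(mode = "heuristic"))
  cand <- enumerate_peptides(prot)
  # binding -> anchors -> similarity
  a <- rank_candidates(filter_binders(cand, cfg), cfg = cfg)
  # anchors first, binding second
  anchored <- cand[anchors_ok(cand$peptide, cfg), , drop = FALSE]
  b <- rank_candidates(filter_binders(anchored, cfg), cfg = cfg)
  expect_identical(a, b)
})
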