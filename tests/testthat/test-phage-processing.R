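test_that("clonotype tables round-trip through both dialects", {
  tab <- tibble::tibble(
    cdr3_aa = c("CASSNLGGLGELFF", "CASSYVGNTGELFF"),
    count = c(7L, 3L),
    v_call = "TRBV6-5*01",
    j_call = "TRBJ2-2*01"
  )
  for (dialect in c("mixcr", "airr")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_clonotype_table(tab, path, dialect)
    back <- read_clonotype_table(path, dialect)
    expect_identical(back$cdr3_aa, tab$cdr3_aa)
    expect_identical(back$count, tab$count)
    expect_identical(back$v_gene, c("TRBV6-5", "TRBV6-5"))
  }
})

test_that("gene calls are normalized by stripping scores and alleles", {
  expect_identical(normalize_gene_call("TRBV6-5*01(1200)"), "TRBV6-5")
  expect_identical(normalize_gene_call(" trbv6-5*01 "), "TRBV6-5")
  expect_identical(normalize_gene_call("TRBV6-5*01(99),TRBV6-6*01(80)"),
                   "TRBV6-5")
  expect_identical(normalize_gene_call("TRBJ2-2"), "TRBJ2-2")
})

test_that("an empty file with a header reads as an empty table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("junction_aa\tv_call\tj_call\tduplicate_count", path)
  tab <- read_clonotype_table(path, "airr")
  expect_identical(nrow(tab), 0L)
})

test_that("missing required columns raise a named error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("aaSeqCDR3", "CASSNLGGLGELFF"), path)
  expect_error(read_clonotype_table(path, "mixcr"), "cloneCount")
  expect_error(read_clonotype_table("no/such/file.tsv", "airr"),
               "not found")
})

test_that("unparseable rows are skipped with a count", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("junction_aa\tv_call\tj_call\tduplicate_count",
               "CASSNLGGLGELFF\tTRBV6-5\tTRBJ2-2\t4",
               "\tTRBV6-5\tTRBJ2-2\t2",
               "CASSXXGELFF\tTRBV6-5\tTRBJ2-2\tnot_a_number"), path)
  expect_message(tab <- read_clonotype_table(path, "airr"), "skipped 2")
  expect_identical(nrow(tab), 1L)
  expect_identical(attr(tab, "n_skipped"), 2L)
})

test_that("quality filters remove singletons, template and bad alphabet", {
  tab <- tibble::tibble(
    cdr3_aa = c("CASSNLGGLGELFF", "CASSAAAAAGELFF", "CASSWWWWWGELFF",
                "CASSYVGNTGELFF", "CASSXX*GELFF"),
    count = c(3L, 1L, 2L, 50L, 9L),
    v_call = "TRBV6-5", j_call = "TRBJ2-2"
  )
  out <- filter_clonotypes(tab, "YVGNT")
  expect_setequal(out$cdr3_aa, c("CASSNLGGLGELFF", "CASSWWWWWGELFF"))
  audit <- attr(out, "audit")
  expect_identical(unname(audit["singleton"]), 1L)
  expect_identical(unname(audit["template"]), 1L)
  expect_identical(unname(audit["alphabet"]), 1L)
  expect_identical(unname(audit["input"]),
                   unname(audit["kept"] + audit["alphabet"] +
                            audit["singleton"] + audit["template"] +
                            audit["dedup"]))
})

test_that("deduplication sums counts and filtering is idempotent", {
  tab <- tibble::tibble(
    cdr3_aa = rep(c("CASSNLGGLGELFF", "CASSWWWWWGELFF"), c(3L, 1L)),
    count = c(2L, 3L, 4L, 5L),
    v_call = "TRBV6-5", j_call = "TRBJ2-2"
  )
  once <- filter_clonotypes(tab, "YVGNT")
  expect_identical(once$count[once$cdr3_aa == "CASSNLGGLGELFF"], 9L)
  twice <- filter_clonotypes(once, "YVGNT")
  expect_identical(twice$cdr3_aa, once$cdr3_aa)
  expect_identical(twice$count, once$count)
})

test_that("filter survivors match an independent brute-force recount", {
  des <- design5()
  cfg <- screen_sim_config(n_input_clonotypes = 1500L,
                           n_output_clonotypes = 1000L,
                           singleton_rate = 0.3, seed = 77L)
  input <- sample_input_library(des, cfg)
  scr <- simulate_panning(input, planted_motif(default_planted_pwm(5L)),
                          cfg, des)
  tab <- scr$output_table
  out <- filter_clonotypes(tab, "YVGNT", des)
  # independent recount (output clonotypes are already unique)
  expected <- sum(tab$count >= 2L &
                    tab$cdr3_aa != "CASSYVGNTGELFF" &
                    grepl("^[ARNDCQEGHILKMFPSTWYV]+$", tab$cdr3_aa))
  expect_identical(nrow(out), expected)
})

test_that("cores are extracted between the flanks and partitioned", {
  tab <- tibble::tibble(
    cdr3_aa = c("CASSNTGGVGELFF", "CASSNLGSGELFF", "CASAYVGNTGELFF",
                "CASSGELFF"),
    count = c(2L, 2L, 2L, 2L),
    v_call = "TRBV6-5", j_call = "TRBJ2-2"
  )
  cores <- extract_cores(tab, library_design())
  expect_identical(cores[["5"]]$core, "NTGGV")
  expect_identical(cores[["4"]]$core, "NLGS")
  expect_identical(attr(cores, "n_excluded"), 2L)
})

test_that("core extraction inverts flank construction on generated data", {
  des <- library_design()
  tab <- sample_input_library(des, screen_sim_config(
    n_input_clonotypes = 400L, seed = 15L))
  cores <- extract_cores(tab, des)
  rebuilt <- unlist(lapply(cores, function(df) {
    paste0("CASS", df$core, "GELFF")
  }), use.names = FALSE)
  expect_setequal(rebuilt, tab$cdr3_aa)
  expect_identical(attr(cores, "n_excluded"), 0L)
})
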