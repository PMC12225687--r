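test_that("input library handles empty and degenerate configurations", {
  des <- design5()
  empty <- sample_input_library(des, screen_sim_config(
    n_input_clonotypes = 0L, seed = 1L))
  expect_identical(nrow(empty), 0L)

  deg_des <- library_design(core_lengths = 5L,
                            aa_composition = point_mass_composition("G"))
  tab <- sample_input_library(deg_des, screen_sim_config(
    n_input_clonotypes = 3L, count_model = list(name = "constant",
                                                mean = 2), seed = 1L))
  expect_identical(tab$cdr3_aa, "CASSGGGGGGELFF")
  expect_identical(tab$count, 6L)
})

test_that("invalid compositions are rejected with a diagnostic", {
  bad <- default_core_composition()
  bad["G"] <- -0.05
  expect_error(library_design(aa_composition = bad), "G")
  short <- default_core_composition()[1:19]
  expect_error(library_design(aa_composition = short), "missing")
  unnorm <- default_core_composition() * 1.01
  expect_error(library_design(aa_composition = unnorm), "sum to 1")
})

test_that("sampled core composition matches the design", {
  des <- design5()
  tab <- sample_input_library(des, screen_sim_config(
    n_input_clonotypes = 10000L, seed = 3L))
  cores <- substr(tab$cdr3_aa, 5L, nchar(tab$cdr3_aa) - 5L)
  comp <- default_core_composition()
  used <- comp[comp > 0]
  counts <- table(factor(unlist(strsplit(cores, "")),
                         levels = names(used)))
  gof <- stats::chisq.test(as.numeric(counts), p = used)
  expect_gt(gof$p.value, 0.01)
})

test_that("simulators are deterministic given config and seed", {
  des <- library_design()
  cfg <- screen_sim_config(n_input_clonotypes = 500L,
                           n_output_clonotypes = 300L, seed = 21L)
  a1 <- sample_input_library(des, cfg)
  a2 <- sample_input_library(des, cfg)
  expect_identical(a1, a2)
  s1 <- simulate_panning(a1, planted_motif(), cfg, des)
  s2 <- simulate_panning(a2, planted_motif(), cfg, des)
  expect_identical(s1$output_table, s2$output_table)
  expect_identical(s1$truth, s2$truth)
  rcfg <- repertoire_sim_config(n_records = 400L, seed = 21L)
  expect_identical(generate_repertoire(rcfg, des),
                   generate_repertoire(rcfg, des))
})

test_that("panning output labels partition the clonotypes", {
  scr <- tiny_screen(seed = 31L)
  expect_identical(nrow(scr$output_table), nrow(scr$truth))
  expect_identical(nrow(scr$output_table), 1500L)
  expect_true(all(scr$truth$label %in% c("binder", "contaminant")))
  expect_false(anyDuplicated(scr$output_table$cdr3_aa) > 0)
})

test_that("pure contamination reproduces the input composition", {
  des <- design5()
  cfg <- screen_sim_config(n_input_clonotypes = 6000L,
                           n_output_clonotypes = 5000L,
                           contamination = 1, seed = 41L)
  input <- sample_input_library(des, cfg)
  scr <- simulate_panning(input, planted_motif(default_planted_pwm(5L)),
                          cfg, des)
  expect_identical(sum(scr$truth$label == "binder"), 0L)
  cores <- substr(scr$output_table$cdr3_aa, 5L,
                  nchar(scr$output_table$cdr3_aa) - 5L)
  freq <- phagetcr:::position_frequencies(cores)
  comp <- default_core_composition()
  for (p in seq_len(5L)) {
    expect_lte(tv_dist(freq[p, ], comp), 0.05)
  }
})

test_that("a point-mass motif at high selection strength dominates", {
  des <- design5()
  pwm <- matrix(0, 5, 20, dimnames = list(NULL, aa_alphabet()))
  for (i in seq_len(5)) pwm[i, strsplit("NLGGL", "")[[1]][i]] <- 1
  cfg <- screen_sim_config(n_input_clonotypes = 500L,
                           n_output_clonotypes = 50L,
                           contamination = 0, seed = 51L)
  input <- sample_input_library(des, cfg)
  scr <- simulate_panning(input, planted_motif(pwm, beta = 50), cfg, des)
  cores <- substr(scr$output_table$cdr3_aa, 5L,
                  nchar(scr$output_table$cdr3_aa) - 5L)
  expect_true(all(cores == "NLGGL"))
})

test_that("planted binder cores follow the planted PWM", {
  # length-7 cores: the 20^7 sequence space is far from saturated, so the
  # unique-clonotype ensemble is an unbiased sample of the PWM (length-5
  # spaces saturate and flatten sharp motifs; see the methods vignette)
  pwm <- default_planted_pwm(7L)
  scr <- tiny_screen(n_input = 6000L, n_output = 5000L, seed = 61L,
                     contamination = 0.5, beta = 1,
                     design = library_design(core_lengths = 7L),
                     pwm = pwm)
  binder_cdr3 <- scr$truth$cdr3_aa[scr$truth$label == "binder"]
  binder_cores <- substr(binder_cdr3, 5L, nchar(binder_cdr3) - 5L)
  freq <- phagetcr:::position_frequencies(binder_cores)
  for (p in seq_len(7L)) {
    expect_lte(tv_dist(freq[p, ], pwm[p, ]), 0.05)
  }
})

test_that("zero selection strength reduces binders to the background", {
  des <- design5()
  cfg <- screen_sim_config(n_input_clonotypes = 3000L,
                           n_output_clonotypes = 2000L,
                           contamination = 0.5, seed = 71L)
  input <- sample_input_library(des, cfg)
  scr <- simulate_panning(input,
                          planted_motif(default_planted_pwm(5L),
                                        beta = 0), cfg, des)
  core_of <- function(x) substr(x, 5L, nchar(x) - 5L)
  b <- core_of(scr$truth$cdr3_aa[scr$truth$label == "binder"])
  cont <- core_of(scr$truth$cdr3_aa[scr$truth$label == "contaminant"])
  tab <- rbind(
    table(factor(unlist(strsplit(b, "")), levels = aa_alphabet())),
    table(factor(unlist(strsplit(cont, "")), levels = aa_alphabet()))
  )
  tab <- tab[, colSums(tab) > 0]
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("repertoire spike-ins are planted exactly once at their indices", {
  des <- library_design()
  spikes <- c("CASSNLGGLGELFF", "CASSYVGNTGELFF", "CASSNTGGVGELFF")
  rcfg <- repertoire_sim_config(n_records = 1000L, spike_in = spikes,
                                seed = 9L)
  rep_tab <- generate_repertoire(rcfg, des)
  expect_identical(sum(rep_tab$is_spike_in), 3L)
  expect_setequal(rep_tab$junction_aa[rep_tab$is_spike_in], spikes)
  for (s in spikes) {
    expect_identical(sum(rep_tab$junction_aa == s), 1L)
  }
  expect_true(all(startsWith(rep_tab$junction_aa, "CASS")))
  expect_true(all(endsWith(rep_tab$junction_aa, "GELFF")))
})

test_that("spike-ins violating the flank convention are rejected", {
  rcfg <- repertoire_sim_config(n_records = 10L,
                                spike_in = "CASAYVGNTGELFF")
  expect_error(generate_repertoire(rcfg, library_design()),
               "flank convention")
})

test_that("repertoire core lengths follow the configured distribution", {
  des <- library_design()
  rcfg <- repertoire_sim_config(n_records = 50000L, seed = 13L)
  rep_tab <- generate_repertoire(rcfg, des)
  core_len <- nchar(rep_tab$junction_aa) - 9L
  dist <- rcfg$core_length_distribution
  counts <- table(factor(core_len, levels = names(dist)))
  gof <- stats::chisq.test(as.numeric(counts), p = dist)
  expect_gt(gof$p.value, 0.01)
})

test_that("panning rejects motifs whose lengths are not in the design", {
  des <- design5()
  input <- sample_input_library(des, screen_sim_config(
    n_input_clonotypes = 100L, seed = 1L))
  expect_error(
    simulate_panning(input, planted_motif(default_planted_pwm(7L)),
                     screen_sim_config(seed = 1L), des),
    "absent")
  expect_error(
    simulate_panning(input[0, ], planted_motif(default_planted_pwm(5L)),
                     screen_sim_config(seed = 1L), des),
    "empty")
})
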