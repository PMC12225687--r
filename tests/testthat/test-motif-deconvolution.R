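test_that("background estimation matches hand counts", {
  expect_error(estimate_background(character()), "empty")

  bg <- estimate_background(rep("GGGGG", 10L), pseudocount = 0.01)
  expect_gt(bg[["G"]], 0.99)
  expect_equal(sum(bg), 1)

  bg2 <- estimate_background(c("AAAAA", "CCCCC"), pseudocount = 0)
  expect_equal(unname(bg2[c("A", "C")]), c(0.5, 0.5))
  expect_equal(sum(bg2), 1)

  set.seed(3)
  cores <- replicate(200, paste(sample(aa_alphabet(), 5, TRUE),
                                collapse = ""))
  bg3 <- estimate_background(cores, pseudocount = 0)
  tally <- table(factor(unlist(strsplit(cores, "")),
                        levels = aa_alphabet()))
  expect_equal(unname(bg3), as.numeric(tally) / sum(tally))
})

test_that("EM on identical sequences converges to a point-mass motif", {
  bg <- stats::setNames(rep(0.05, 20), aa_alphabet())
  fit <- fit_mixture(rep("NLGGL", 100L), k = 1L, background = bg,
                     seed = 7L)
  expect_gt(fit$weights[["motif1"]], 0.95)
  pwm <- fit$pwm[[1]]
  consensus <- strsplit("NLGGL", "")[[1]]
  for (p in 1:5) {
    expect_gt(pwm[p, consensus[p]], 0.95)
  }
  # restart stability on this fixture
  fit2 <- fit_mixture(rep("NLGGL", 100L), k = 1L, background = bg,
                      seed = 99L)
  expect_lt(abs(fit$loglik - fit2$loglik) / abs(fit$loglik), 1e-6)
})

test_that("EM trace is monotone and estimates stay on the simplex", {
  scr <- tiny_screen(seed = 83L)
  out_cores <- extract_cores(filter_clonotypes(scr$output_table, "YVGNT",
                                               design5()), design5())
  bg <- estimate_background(extract_cores(
    filter_clonotypes(scr$input_table, "YVGNT", design5()), design5()))
  fit <- fit_mixture(out_cores[["5"]]$core, k = 1L, background = bg,
                     seed = 5L)
  expect_true(all(diff(fit$trace) >= -1e-7 * abs(fit$loglik)))
  expect_equal(sum(fit$weights), 1)
  expect_true(all(fit$weights >= 0))
  expect_equal(unname(rowSums(fit$responsibilities)),
               rep(1, nrow(fit$responsibilities)))
  expect_true(all(fit$responsibilities >= 0))
  expect_true(all(vapply(fit$pwm, function(m) {
    all(abs(rowSums(m) - 1) < 1e-9) && all(m > 0)
  }, logical(1))))
})

test_that("information content has its closed-form values", {
  uniform <- stats::setNames(rep(0.05, 20), aa_alphabet())
  flat_pwm <- matrix(0.05, 3, 20, dimnames = list(NULL, aa_alphabet()))
  expect_equal(position_information_content(flat_pwm, uniform),
               rep(0, 3))

  point <- matrix(0, 1, 20, dimnames = list(NULL, aa_alphabet()))
  point[1, "W"] <- 1
  expect_equal(position_information_content(point, uniform), log2(20))

  half_bg <- stats::setNames(c(0.5, rep(0.5 / 19, 19)),
                             c("W", setdiff(aa_alphabet(), "W")))
  expect_equal(position_information_content(point, half_bg), 1)

  expect_error(
    position_information_content(point, stats::setNames(
      c(0, rep(1 / 19, 19)), aa_alphabet())),
    "zero")
})

test_that("background-only screens fail the information gate", {
  des <- design5()
  cfg <- screen_sim_config(n_input_clonotypes = 2500L,
                           n_output_clonotypes = 2000L,
                           contamination = 1, seed = 19L)
  input <- sample_input_library(des, cfg)
  scr <- simulate_panning(input, planted_motif(default_planted_pwm(5L)),
                          cfg, des)
  out_cores <- extract_cores(filter_clonotypes(scr$output_table, "YVGNT",
                                               des), des)
  bg <- estimate_background(extract_cores(
    filter_clonotypes(input, "YVGNT", des), des))
  fit <- fit_mixture(out_cores[["5"]]$core, k = 1L, background = bg,
                     seed = 23L)
  res <- classify_binders(fit)
  expect_lt(max(res$ic[[1]]), 1)
  expect_false(res$ic_pass[[1]])
  expect_length(res$binders, 0L)
  expect_identical(sort(res$contaminants), sort(fit$cores))
})

test_that("planted screens are deconvolved with high fidelity", {
  # length-7 screen: recovery is evaluated where the unique-clonotype
  # ensemble is an unbiased PWM sample (length-5 spaces saturate)
  pwm <- default_planted_pwm(7L)
  des <- library_design(core_lengths = 7L)
  cfg <- screen_sim_config(n_input_clonotypes = 8000L,
                           n_output_clonotypes = 5000L,
                           contamination = 0.5, seed = 29L)
  input <- sample_input_library(des, cfg)
  scr <- simulate_panning(input, planted_motif(pwm, beta = 1), cfg, des)
  out_cores <- extract_cores(scr$output_table, des)
  bg <- estimate_background(extract_cores(input, des))
  fit <- fit_mixture(out_cores[["7"]]$core, k = 1L, background = bg,
                     seed = 31L)
  res <- classify_binders(fit)
  expect_true(res$ic_pass[[1]])

  # PWM recovery within per-position total variation 0.1
  for (p in 1:7) {
    expect_lte(tv_dist(fit$pwm[[1]][p, ], pwm[p, ]), 0.1)
  }

  # binder/contaminant assignment against truth labels
  truth_label <- scr$truth$label[match(
    paste0("CASS", fit$cores, "GELFF"), scr$truth$cdr3_aa)]
  pred_binder <- fit$cores %in% res$binders
  tp <- sum(pred_binder & truth_label == "binder")
  prec <- tp / sum(pred_binder)
  rec <- tp / sum(truth_label == "binder")
  f1 <- 2 * prec * rec / (prec + rec)
  expect_gte(prec, 0.9)
  expect_gte(rec, 0.9)
  expect_gte(f1, 0.9)
})

test_that("nearly pure binder screens classify almost everything binder", {
  scr <- tiny_screen(n_input = 3000L, n_output = 2000L,
                     contamination = 0, seed = 37L)
  des <- design5()
  out_cores <- extract_cores(filter_clonotypes(scr$output_table, "YVGNT",
                                               des), des)
  bg <- estimate_background(extract_cores(
    filter_clonotypes(scr$input_table, "YVGNT", des), des))
  fit <- fit_mixture(out_cores[["5"]]$core, k = 1L, background = bg,
                     seed = 41L)
  res <- classify_binders(fit)
  expect_gte(length(res$binders) / length(fit$cores), 0.99)
})

test_that("degenerate models and bad inputs are handled", {
  expect_error(fit_mixture(c("AAAAA"), k = 1L,
                           background = stats::setNames(rep(0.05, 20),
                                                        aa_alphabet())),
               "at least")
  # hand-built model: all responsibility on a sharp motif
  fake <- structure(list(
    pwm = list(local({
      m <- matrix(1e-6, 5, 20, dimnames = list(NULL, aa_alphabet()))
      for (i in 1:5) m[i, strsplit("NLGGL", "")[[1]][i]] <- 1 - 19e-6
      m
    })),
    background = stats::setNames(rep(0.05, 20), aa_alphabet()),
    weights = c(flat = 0, motif1 = 1),
    responsibilities = matrix(c(0, 1), 10, 2, byrow = TRUE,
                              dimnames = list(NULL, c("flat", "motif1"))),
    cores = rep("NLGGL", 10L),
    k = 1L), class = "pwm_mixture")
  res <- classify_binders(fake)
  expect_length(res$contaminants, 0L)
  expect_identical(res$binders, rep("NLGGL", 10L))
})

test_that("per-length deconvolution covers every length present", {
  scr <- tiny_screen(n_input = 3000L, n_output = 1500L, seed = 43L,
                     design = library_design(),
                     pwm = default_planted_pwms())
  des <- library_design()
  out_cores <- extract_cores(filter_clonotypes(scr$output_table, "YVGNT",
                                               des), des)
  in_cores <- extract_cores(filter_clonotypes(scr$input_table, "YVGNT",
                                              des), des)
  res <- deconvolve_cores(out_cores, in_cores, seed = 47L)
  expect_setequal(names(res), names(out_cores))
  for (len in names(res)) {
    expect_setequal(c(res[[len]]$binders, res[[len]]$contaminants),
                    out_cores[[len]]$core)
  }
})
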