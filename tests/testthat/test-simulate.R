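test_that("error models validate their rates", {
  expect_error(error_model_uniform(-0.1), "probability")
  expect_error(error_model_uniform(c(0.1, 0.2)), "single")
  expect_error(error_model_positional(c(0.1, 1.5)), "probabilities")
  expect_equal(rates_for_length(error_model_uniform(0.05), 4), rep(0.05, 4))
  expect_error(rates_for_length(error_model_positional(rep(0.1, 10)), 50),
               "read length is 50")
})

test_that("the measured per-cycle error model has 50 rising rates", {
  m <- real_world_error_model()
  r <- m$rates
  expect_length(r, 50)
  expect_equal(r[1:3], c(0.014, 0.005, 0.006))
  expect_equal(r[50], 0.184)
  expect_true(all(r > 0 & r < 0.2))
  # rates climb over the read: last-decile mean far above first-decile mean
  expect_gt(mean(r[41:50]), 5 * mean(r[1:10]))
})

test_that("read sampling honors the flanked-window contract", {
  sk <- sample_reads("random", 5, 25, seed = 5)
  expect_length(sk, 5)
  for (s in sk) {
    expect_equal(nchar(s$sequence), 25L)
    expect_equal(nchar(s$reference), 45L)
    expect_equal(substr(s$reference, 11, 35), s$sequence)
    expect_true(is.na(s$source_pos))
  }
  src <- paste(rep("ACGT", 40), collapse = "")
  sk2 <- sample_reads(src, 20, 30, seed = 7)
  for (s in sk2) {
    expect_equal(nchar(s$reference), 50L)
    expect_equal(substr(src, s$source_pos, s$source_pos + 29L), s$sequence)
  }
  expect_error(sample_reads("ACGT", 1, 25), "shorter")
  expect_warning(sample_reads(paste0(strrep("N", 5), src), 1, 25, seed = 1),
                 "non-ACGT")
})

test_that("SNP injection picks distinct positions and wrong bases", {
  set.seed(311)
  for (rep in 1:30) {
    x <- random_seq(40)
    n_snps <- sample(0:3, 1)
    r <- inject_snps(x, n_snps)
    expect_equal(nrow(r$snps), n_snps)
    expect_equal(anyDuplicated(r$snps$pos), 0L)
    xb <- strsplit(x, "")[[1]]; yb <- strsplit(r$sequence, "")[[1]]
    expect_equal(which(xb != yb), r$snps$pos)
    expect_true(all(r$snps$from != r$snps$to))
  }
})

test_that("color error injection is Bernoulli per position with wrong values", {
  er <- encode_read(random_seq(200), k = 2)
  set.seed(313)
  r0 <- inject_color_errors(er, error_model_uniform(0))
  expect_identical(r0$read$colors, er$colors)
  r1 <- inject_color_errors(er, error_model_uniform(1))
  expect_true(all(r1$read$colors != er$colors))
  expect_equal(nrow(r1$errors), 200L)
  # rate 0.1 over 200 colors: within a generous binomial envelope
  hits <- replicate(20, nrow(inject_color_errors(er,
                                                 error_model_uniform(0.1))$errors))
  expect_gt(mean(hits), 10)
  expect_lt(mean(hits), 30)
})

test_that("base error injection avoids the excluded SNP positions", {
  set.seed(317)
  x <- random_seq(60)
  r <- inject_base_errors(x, error_model_uniform(1), exclude = c(5L, 20L))
  expect_false(any(c(5L, 20L) %in% r$errors$pos))
  expect_equal(sort(r$errors$pos), setdiff(1:60, c(5L, 20L)))
  expect_true(all(r$errors$from != r$errors$to))
})

test_that("a clean error-free cell has power 1 and zero false positives", {
  cfg <- simulation_config(k = 2, read_length = 25, n_reads = 40, seed = 31)
  res <- run_experiment(cfg)
  expect_equal(res$power, 1)
  expect_equal(res$fp_snp_rate, 0)
  expect_true(is.na(res$fn_snp_rate))
})

test_that("experiments are exactly reproducible from the seed", {
  cfg <- simulation_config(k = 2, read_length = 25, n_reads = 30, seed = 99,
                           error_model = error_model_uniform(0.05), n_snps = 1)
  a <- run_experiment(cfg)
  b <- run_experiment(cfg)
  expect_identical(a$per_read, b$per_read)
  cfg2 <- simulation_config(k = 2, read_length = 25, n_reads = 30, seed = 100,
                            error_model = error_model_uniform(0.05), n_snps = 1)
  c <- run_experiment(cfg2)
  expect_false(identical(a$per_read$score, c$per_read$score))
})

test_that("an error-free SNP is missed only for a strictly better explanation", {
  # a SNP can evade its k-color signature in two legitimate ways: a
  # truncated signature in the last k-1 bases (rescored as one cheaper
  # color error) or a lucky flank realignment absorbing it into a gap;
  # both score strictly above the generative trace
  cfg <- simulation_config(k = 2, read_length = 25, n_snps = 1, n_reads = 60,
                           seed = 37)
  res <- run_experiment(cfg, keep_reads = TRUE)
  expect_true(is.na(res$fp_snp_rate))
  expect_true(all(res$per_read$score >= res$per_read$true_score))
  missed <- res$per_read$injected_snps_called == 0L
  expect_true(all(res$per_read$score[missed] > res$per_read$true_score[missed]))
  # most reads keep the generative optimum and call the SNP
  expect_gt(mean(!missed), 0.8)
})

test_that("the generative true score matches a direct rescore", {
  set.seed(41)
  sk <- sample_reads("random", 1, 25)[[1]]
  sim <- simulate_read(sk, k = 2, n_snps = 1,
                       error_model = error_model_uniform(0.05))
  ev <- evaluate_read(sim)
  # the optimum can only improve on the generative trace
  expect_gte(ev$score, sim$true_score)
  s <- default_scheme()
  # gap-free truth: base scores plus color scores, one CE per injected error
  expect_equal(sim$true_score,
               (25L - nrow(sim$snps)) * s$base_match +
                 nrow(sim$snps) * s$base_mismatch +
                 (25L - nrow(sim$errors)) * s$color_match +
                 nrow(sim$errors) * s$color_mismatch)
})

test_that("k = 1 cells use base errors and standard base-space alignment", {
  cfg <- simulation_config(k = 1, read_length = 25, n_reads = 30, seed = 43,
                           error_model = error_model_uniform(0.1), n_snps = 1)
  res <- run_experiment(cfg, keep_reads = TRUE)
  for (sim in res$reads) {
    expect_equal(sim$k, 1L)
    # base errors never sit on a SNP position
    expect_false(any(sim$errors$pos %in% sim$snps$pos))
  }
  # at k = 1 every base error is indistinguishable from a SNP, so with a 10%
  # error rate most reads call spurious SNPs and power is well below 1
  expect_lt(res$power, 1)
})

test_that("fn_mode distinguishes none-called from any-missed", {
  base <- list(k = 2, read_length = 25, n_snps = 2, n_reads = 60, seed = 47,
               error_model = error_model_uniform(0.08))
  a <- run_experiment(do.call(simulation_config,
                              c(base, fn_mode = "none_called")))
  b <- run_experiment(do.call(simulation_config,
                              c(base, fn_mode = "any_missed")))
  # any-missed is at least as strict as none-called
  expect_gte(b$fn_snp_rate, a$fn_snp_rate)
})

test_that("simulation configs reject impossible cells", {
  expect_error(simulation_config(n_snps = 30, read_length = 25),
               "0..read_length")
  expect_error(simulation_config(k = 0), "k")
})
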