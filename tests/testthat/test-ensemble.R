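# Prior grid, high-PP QTL calling, occurrence rates, analysis selection.

test_that("the prior grid has 11 values with the printed endpoints", {
  g <- build_prior_grid(0.93)
  expect_length(g, 11L)
  expect_true(any(abs(g - 0.05) < 1e-12))
  expect_true(any(abs(g - 6.25e-5) < 1e-12))
  expect_true(all(g > 0 & g < 1))
  expect_true(all(diff(g) < 0))  # sorted descending
})

test_that("pSSR-derived priors are half, full and capped double", {
  g <- build_prior_grid(0.99)
  src <- attr(g, "source")
  expect_equal(sort(as.numeric(g[src != "fixed"])), c(0.005, 0.01, 0.02),
               tolerance = 1e-12)
  # doubling is capped at 0.5 (the collision with 1 - p_ssr is perturbed)
  g2 <- suppressWarnings(build_prior_grid(0.5))
  expect_equal(max(g2[attr(g2, "source") == "pssr_double"]), 0.5)
  expect_error(build_prior_grid(1), "p_ssr")
  expect_error(build_prior_grid(0), "p_ssr")
})

test_that("high-PP QTL use a strict threshold and merge overlapping windows", {
  D <- matrix(0L, 10, 8)
  D[1:5, 3] <- 1L             # SNP3 PP 0.5 -> its windows at most 0.5
  D[1:8, 6] <- 1L             # SNP6 PP 0.8
  ch <- make_chain(D)
  pp <- compute_pp(ch, burn_in = 0, window = 2)
  qtl <- call_high_pp_qtl(pp, threshold = 0.5)
  # windows (5,6) and (6,7) exceed 0.5 and share SNP6 -> one merged QTL;
  # windows containing only SNP3 sit exactly at 0.5 and are not called
  expect_equal(nrow(qtl), 1L)
  expect_setequal(qtl$snp_ids[[1]], c("s005", "s006", "s007"))

  expect_equal(nrow(call_high_pp_qtl(pp, threshold = 0.9)), 0L)
})

test_that("raising the PP threshold never increases the QTL count", {
  st <- small_study(seed = 81)
  cfg <- bayesb_config(one_minus_pi = 0.1, n_iterations = 2000, thin = 20,
                       seed = 2)
  ch <- run_bayesb(st$genotypes, st$phenotypes, cfg)
  pp <- compute_pp(ch, burn_in = 10)
  counts <- vapply(c(0.2, 0.5, 0.8), function(th)
    nrow(call_high_pp_qtl(pp, th)), integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("occurrence rates count analyses via transitive member overlap", {
  # QTL present (same members) in analyses 1, 3 of 3 -> rate 2
  qa <- .toy_qtl(list(c("s1", "s2")))
  qb <- .toy_qtl(list(c("s9")))
  qc_ <- .toy_qtl(list(c("s2", "s3")))
  rated <- occurrence_rates(list(qa, qb, qc_))
  expect_equal(rated[[1]]$occurrence_rate, 2L)  # s1s2 ~ s2s3
  expect_equal(rated[[2]]$occurrence_rate, 1L)
  expect_equal(rated[[3]]$occurrence_rate, 2L)

  # chained overlap A~B, B~C, A!~C -> one cluster
  qa2 <- .toy_qtl(list(c("s1", "s2")))
  qb2 <- .toy_qtl(list(c("s2", "s3")))
  qc2 <- .toy_qtl(list(c("s3", "s4")))
  rated2 <- occurrence_rates(list(qa2, qb2, qc2))
  expect_equal(unique(unlist(lapply(rated2, `[[`, "cluster"))), 1L)
  expect_true(all(unlist(lapply(rated2, `[[`, "occurrence_rate")) == 3L))

  # disjoint spans stay separate QTL with rate 1
  rated3 <- occurrence_rates(list(.toy_qtl(list("s1")), .toy_qtl(list("s8"))))
  expect_equal(rated3[[1]]$occurrence_rate, 1L)
  expect_equal(rated3[[2]]$occurrence_rate, 1L)
})

test_that("the analysis with the highest average occurrence rate wins", {
  a <- .toy_qtl(list(c("s1"), c("s5")))
  a$occurrence_rate <- c(3L, 3L)                # avg 3
  b <- .toy_qtl(list(c("s1"), c("s9")))
  b$occurrence_rate <- c(11L, 1L)               # avg 6
  sel <- select_analysis(list(a, b), priors = c(0.05, 0.01))
  expect_equal(sel$selected, 2L)
  expect_equal(sel$avg_rates, c(3, 6))

  # single non-empty analysis
  sel2 <- select_analysis(list(.toy_qtl(list()), b), priors = c(0.05, 0.01))
  expect_equal(sel2$selected, 2L)

  # exact tie -> larger prior association probability, with warning
  b2 <- data.table::copy(a)
  expect_warning(
    sel3 <- select_analysis(list(a, b2), priors = c(0.01, 0.05)),
    "tie")
  expect_equal(sel3$selected, 2L)

  expect_error(select_analysis(list(.toy_qtl(list()), .toy_qtl(list())),
                               priors = c(0.05, 0.01)),
               "no high PP QTL")
})

test_that("every selected-analysis QTL has occurrence rate at least 1", {
  st <- small_study(seed = 82)
  qc <- qc_pipeline(st$genotypes, st$pedigree, st$phenotypes)
  vc <- estimate_varcomp(qc$phenotypes, st$amatrix)
  scan <- ssr_scan(qc$genotypes, qc$phenotypes, st$amatrix, vc)
  qres <- qvalues(scan$p)
  # ties on the average occurrence rate are routine at this toy scale
  ens <- suppressWarnings(
    run_ensemble(qc$genotypes, qc$phenotypes, p_ssr = qres$p_ssr,
                 base_cfg = bayesb_config(0.01, n_iterations = 1500,
                                          thin = 50, seed = 4)))
  expect_length(ens$priors, 11L)
  if (!is.na(ens$selected) && nrow(ens$qtl)) {
    expect_true(all(ens$qtl$occurrence_rate >= 1L))
    expect_equal(ens$avg_rates[ens$selected], max(ens$avg_rates))
  }
})
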