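test_that("position filter removes sex-chromosome and unplaced SNPs", {
  X <- matrix(1, 4, 3, dimnames = list(letters[1:4], NULL))
  gs <- genotype_set(X, data.frame(chrom = c("1", "X", "1"),
                                   snp_id = c("a1", "x1", "a0"),
                                   pos = c(100L, 100L, 0L)))
  out <- filter_unmapped(gs)
  expect_setequal(out$report$removed_snps, c("x1", "a0"))
  expect_equal(out$genotypes$snp_ids, "a1")
})

test_that("Mendelian filter keys on opposing homozygotes only", {
  ped <- pedigree(data.frame(animal = c("s", "k1", "k2"),
                             sire = c(NA, "s", "s"), dam = c(NA, NA, NA)))
  X <- rbind(s = c(2, 1, 2), k1 = c(0, 0, 2), k2 = c(1, 2, 2))
  gs <- make_gs(X)
  chk <- mendel_check(gs, ped)
  # SNP1: sire 2 vs k1 0 -> violation; SNP2: sire het -> never; SNP3: none
  expect_equal(chk$violations, c(1L, 0L, 0L))
  out <- filter_mendelian(gs, ped, max_error_rate = 0)
  expect_equal(out$report$removed_snps, "s001")
  # tolerance: 1 violation in 2 checkable pairs passes at 60%
  out2 <- filter_mendelian(gs, ped, max_error_rate = 0.6)
  expect_length(out2$report$removed_snps, 0)
})

test_that("a sub-threshold violation rate is tolerated when configured", {
  set.seed(21)
  n_pairs <- 100
  sires <- sprintf("s%03d", 1:n_pairs); kids <- sprintf("k%03d", 1:n_pairs)
  ped <- pedigree(data.frame(animal = c(sires, kids),
                             sire = c(rep(NA, n_pairs), sires),
                             dam = NA))
  g_s <- rep(1, n_pairs); g_k <- rep(1, n_pairs)
  g_s[1] <- 2; g_k[1] <- 0  # exactly one opposing-homozygote pair
  X <- matrix(c(g_s, g_k), ncol = 1,
              dimnames = list(c(sires, kids), NULL))
  gs <- make_gs(X)
  chk <- mendel_check(gs, ped)
  expect_equal(chk$violations, 1L)
  expect_equal(chk$checkable, 100L)
  expect_length(filter_mendelian(gs, ped, 0.02)$report$removed_snps, 0)
  expect_equal(filter_mendelian(gs, ped, 0)$report$removed_snps, "s001")
})

test_that("MAF filter is strict-less-than with all-missing reported", {
  # 100 animals: {0:90, 1:10} -> f = 0.05 retained; {0:95, 1:5} -> 0.025 removed
  X <- cbind(c(rep(1, 10), rep(0, 90)),
             c(rep(1, 5), rep(0, 95)),
             rep(0, 100),
             NA)
  gs <- make_gs(X)
  out <- filter_maf(gs, 0.05)
  expect_equal(out$genotypes$snp_ids, "s001")
  expect_setequal(out$report$removed_snps, c("s002", "s003", "s004"))
  expect_equal(out$report$detail$all_missing, "s004")
})

test_that("call-rate filter is strict-greater-than on the missing fraction", {
  X <- cbind(c(rep(NA, 5), rep(1, 95)),
             c(rep(NA, 6), rep(1, 94)),
             rep(1, 100))
  X[1, 3] <- 0; X[2, 3] <- 2  # keep SNP3 polymorphic-ish, fully called
  gs <- make_gs(X)
  out <- filter_callrate(gs, 0.05)
  expect_equal(out$report$removed_snps, "s002")
  expect_setequal(out$genotypes$snp_ids, c("s001", "s003"))
})

test_that("adjusted reliability follows the parent-average removal formula", {
  expect_equal(adjusted_reliability(0.9, NA, NA), 0.9)
  expect_equal(adjusted_reliability(0.9, 1, 1), (0.9 - 0.5) / (1 - 0.5))
  expect_equal(adjusted_reliability(0.5, 1, 1), 0)          # r2 == r2_PA
  expect_equal(adjusted_reliability(0.3, 1, 1), 0)          # floored at 0
  expect_equal(adjusted_reliability(0.8, 0.8, NA), (0.8 - 0.2) / 0.8)
  expect_error(adjusted_reliability(0.9, 2, 1), "\\[0,1\\]")
})

test_that("animal filter removes low adjusted reliability per trait, strictly", {
  ped <- pedigree(data.frame(animal = c("s", "d", "k1", "k2", "k3"),
                             sire = c(NA, NA, "s", "s", NA),
                             dam = c(NA, NA, "d", "d", NA)))
  ph <- phenotype_table(data.frame(
    animal = c("s", "d", "k1", "k2", "k3"), trait = "cwt",
    drp = 0, reliability = c(1, 1, 0.85, 0.9, 0.70)))
  # k1: (0.85-0.5)/0.5 = 0.70 -> retained (strict <); k2: 0.8 retained
  out <- filter_animals(ph, ped, 0.70)
  expect_true(all(c("k1", "k2", "k3") %in% out$phenotypes$animal))
  ph2 <- phenotype_table(data.frame(
    animal = c("s", "d", "k1"), trait = "cwt",
    drp = 0, reliability = c(1, 1, 0.84)))
  out2 <- filter_animals(ph2, ped, 0.70)  # (0.84-0.5)/0.5 = 0.68 -> removed
  expect_false("k1" %in% out2$phenotypes$animal)
})

test_that("qc pipeline applies filters in order with conserved counts", {
  st <- small_study(seed = 22, missing_rate = 0.08, mendel_error_rate = 0.01)
  qc <- qc_pipeline(st$genotypes, st$pedigree, st$phenotypes,
                    mendel_max = 0.05)
  n_removed <- sum(vapply(qc$report$stages[1:4], function(s)
    length(s$removed_snps), integer(1)))
  expect_equal(qc$report$n_snps_in - n_removed, qc$report$n_snps_out)
  stages <- vapply(qc$report$stages, `[[`, character(1), "filter")
  expect_equal(stages, c("unmapped", "mendelian", "maf", "callrate",
                         "adjusted_reliability"))
  # removed sets are disjoint across stages
  sets <- lapply(qc$report$stages[1:4], `[[`, "removed_snps")
  expect_equal(anyDuplicated(unlist(sets)), 0L)
})

test_that("on clean simdata only the MAF filter can remove SNPs", {
  st <- small_study(seed = 23)  # mendel_error_rate = 0, missing_rate = 0
  qc <- qc_pipeline(st$genotypes, st$pedigree, st$phenotypes)
  byf <- setNames(lapply(qc$report$stages, `[[`, "removed_snps"),
                  vapply(qc$report$stages, `[[`, character(1), "filter"))
  expect_length(byf$unmapped, 0)
  expect_length(byf$mendelian, 0)
  expect_length(byf$callrate, 0)
})

test_that("SNP filters are idempotent", {
  st <- small_study(seed = 24, missing_rate = 0.05)
  once <- filter_maf(st$genotypes)$genotypes
  twice <- filter_maf(once)
  expect_length(twice$report$removed_snps, 0)
  once_cr <- filter_callrate(st$genotypes, 0.03)$genotypes
  expect_length(filter_callrate(once_cr, 0.03)$report$removed_snps, 0)
})
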