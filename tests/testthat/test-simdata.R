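test_that("smallest and degenerate pedigrees have the expected shape", {
  cfg <- sim_config(n_founders = 2, n_generations = 1, offspring_per_mating = 1)
  trio <- simulate_pedigree(cfg, seed = 1)
  expect_equal(nrow(trio), 3L)
  kid <- trio[!is.na(trio$sire)]
  expect_equal(nrow(kid), 1L)
  expect_setequal(c(kid$sire, kid$dam), trio$animal[trio$generation == 0])

  cfg0 <- sim_config(n_founders = 5, n_generations = 0)
  founders <- simulate_pedigree(cfg0, seed = 1)
  expect_equal(nrow(founders), 5L)
  expect_true(all(is.na(founders$sire)) && all(is.na(founders$dam)))

  expect_error(simulate_pedigree(sim_config(n_founders = 1)), "2 founders")
})

test_that("non-founder parents always precede their offspring", {
  cfg <- sim_config(n_founders = 10, n_generations = 3, seed = 3)
  ped <- simulate_pedigree(cfg)
  pos <- setNames(seq_len(nrow(ped)), ped$animal)
  nf <- ped[!is.na(ped$sire)]
  expect_true(all(pos[nf$sire] < pos[nf$animal]))
  expect_true(all(pos[nf$dam] < pos[nf$animal]))
  expect_false(anyDuplicated(ped$animal) > 0)
  # acyclicity: pedigree() would have refused a cyclic graph
  expect_s3_class(pedigree(as.data.frame(ped)[, c("animal", "sire", "dam")]),
                  "pedigree")
})

test_that("uncorrupted gene dropping is Mendelian-consistent at every SNP", {
  cfg <- sim_config(n_founders = 20, n_generations = 3,
                    n_chromosomes = 2, snps_per_chromosome = 50,
                    mendel_error_rate = 0, missing_rate = 0, seed = 5)
  ped <- simulate_pedigree(cfg)
  gs <- simulate_genotypes(ped, cfg)
  chk <- mendel_check(gs, ped)
  expect_true(all(chk$violations == 0L))
  expect_true(all(chk$checkable > 0L))
})

test_that("ld_rho = 0 gives uncorrelated adjacent founder haplotypes", {
  cfg <- sim_config(n_founders = 5000, n_generations = 0,
                    n_chromosomes = 1, snps_per_chromosome = 20,
                    maf_low = 0.2, maf_high = 0.5, ld_rho = 0, seed = 6)
  set.seed(6)
  H <- pedgwas:::.founder_haplotypes(10000, runif(20, 0.2, 0.5), 0)
  r <- vapply(1:19, function(j) cor(H[, j], H[, j + 1]), numeric(1))
  expect_true(all(abs(r) < 0.1))
})

test_that("ld_rho sets the adjacent-haplotype correlation", {
  set.seed(7)
  H <- pedgwas:::.founder_haplotypes(20000, rep(0.3, 10), 0.6)
  r <- vapply(1:9, function(j) cor(H[, j], H[, j + 1]), numeric(1))
  expect_true(all(abs(r - 0.6) < 0.05))
})

test_that("founder allele frequencies respect the configured MAF bounds", {
  cfg <- sim_config(n_founders = 500, n_generations = 0,
                    n_chromosomes = 1, snps_per_chromosome = 40,
                    maf_low = 0.5, maf_high = 0.5, ld_rho = 0,
                    mendel_error_rate = 0, missing_rate = 0, seed = 8)
  ped <- simulate_pedigree(cfg)
  gs <- simulate_genotypes(ped, cfg)
  f <- colMeans(gs$calls) / 2
  n_al <- 2 * nrow(gs$calls)
  # within 3 binomial SDs of 0.5
  expect_true(all(abs(f - 0.5) < 3 * sqrt(0.25 / n_al)))
})

test_that("gene dropping preserves founder allele frequencies", {
  cfg <- sim_config(n_founders = 200, n_generations = 3,
                    n_chromosomes = 1, snps_per_chromosome = 30,
                    maf_low = 0.2, maf_high = 0.4,
                    mendel_error_rate = 0, missing_rate = 0, seed = 9)
  ped <- simulate_pedigree(cfg)
  gs <- simulate_genotypes(ped, cfg)
  founders <- ped$animal[is.na(ped$sire)]
  last_gen <- ped$animal[ped$generation == max(ped$generation)]
  f0 <- colMeans(gs$calls[founders, ]) / 2
  f1 <- colMeans(gs$calls[last_gen, ]) / 2
  # binomial drift accumulates over the generations walked
  sd_drift <- sqrt(f0 * (1 - f0) / (2 * length(last_gen))) *
    sqrt(max(ped$generation))
  expect_true(all(abs(f1 - f0) < 4 * pmax(sd_drift, 0.02)))
})

test_that("QTL effects follow the scaled inverse chi-squared law", {
  # moment oracle: mean of scaled inv-chi^2(nu, S) is nu*S/(nu-2)
  set.seed(10)
  v <- rscaled_invchisq(10000, 4.234, 0.0429)
  expect_equal(mean(v), 4.234 * 0.0429 / (4.234 - 2), tolerance = 0.1)

  st <- small_study(seed = 12)
  cfg0 <- st$cfg; cfg0$n_qtl <- 0
  eff0 <- simulate_qtl_effects(st$genotypes, cfg0)
  expect_true(all(eff0$effects == 0))

  cfgall <- st$cfg; cfgall$n_qtl <- length(st$genotypes$snp_ids)
  effall <- simulate_qtl_effects(st$genotypes, cfgall)
  expect_true(all(effall$effects != 0))
  cfgbad <- st$cfg; cfgbad$n_qtl <- length(st$genotypes$snp_ids) + 1
  expect_error(simulate_qtl_effects(st$genotypes, cfgbad), "n_qtl")
})

test_that("phenotypes are exact at reliability 1 and track g otherwise", {
  cfg <- sim_config(n_founders = 30, n_generations = 2,
                    n_chromosomes = 2, snps_per_chromosome = 50, n_qtl = 5,
                    rel_low = 1, rel_high = 1,
                    mendel_error_rate = 0, missing_rate = 0, seed = 13)
  st <- simulate_study(cfg)
  expect_equal(st$phenotypes$drp, st$phenotypes$true_g)

  # slope of y on g near 1 at realistic reliabilities
  cfg2 <- sim_config(n_founders = 250, n_generations = 2,
                     n_chromosomes = 2, snps_per_chromosome = 100, n_qtl = 10,
                     h2_polygenic = 0.3, mendel_error_rate = 0,
                     missing_rate = 0, seed = 14)
  st2 <- simulate_study(cfg2)
  fit <- lm(drp ~ true_g, data = st2$phenotypes)
  expect_gt(coef(fit)[2], 0.9)
  expect_lt(coef(fit)[2], 1.1)
})

test_that("pure-noise phenotypes arise with no QTL and no polygene", {
  cfg <- sim_config(n_founders = 50, n_generations = 1, n_chromosomes = 1,
                    snps_per_chromosome = 20, n_qtl = 0, h2_polygenic = 0,
                    mendel_error_rate = 0, missing_rate = 0, seed = 15)
  st <- simulate_study(cfg)
  expect_true(all(st$phenotypes$true_g == 0))
  expect_gt(var(st$phenotypes$drp), 0)  # pure noise around 0
  expect_lt(abs(mean(st$phenotypes$drp)), 0.5)
})

test_that("annotations: multiplicities, spike construction and empty case", {
  st <- small_study(seed = 16)
  ann <- st$annotations
  mult <- table(factor(
    vapply(ann$genes$gene_id,
           function(g) sum(ann$orthologs$bovine == g), numeric(1)),
    levels = 0:2)) / nrow(ann$genes)
  # multinomial CI at ~180 genes: within 4 SDs of configured proportions
  props <- st$cfg$ortholog_props
  se <- sqrt(props * (1 - props) / nrow(ann$genes))
  expect_true(all(abs(as.numeric(mult) - props) < 4 * se + 0.02))

  # spike fraction 1: every spiked-pathway gene is near a true QTL
  cfg1 <- st$cfg; cfg1$spike_fraction <- 1
  ann1 <- simulate_annotations(st$genotypes, st$effects, cfg1)
  qtl_map <- st$genotypes$map[st$effects$qtl_idx]
  near_genes <- ann1$genes[
    vapply(seq_len(nrow(ann1$genes)), function(i)
      any(qtl_map$chrom == ann1$genes$chrom[i] &
            qtl_map$pos >= ann1$genes$start[i] - 5e5 &
            qtl_map$pos <= ann1$genes$end[i] + 5e5), logical(1))]
  near_orth <- unique(ann1$orthologs[ann1$orthologs$bovine %in% near_genes$gene_id]$human)
  spiked <- ann1$pathways$sets[[ann1$spiked_pathway]]
  expect_true(all(spiked %in% near_orth))

  cfg0 <- st$cfg; cfg0$genes_per_chromosome <- 0L
  ann0 <- simulate_annotations(st$genotypes, st$effects, cfg0)
  expect_equal(nrow(ann0$genes), 0L)
  expect_null(ann0$pathways)
})

test_that("the generator is bit-reproducible given (cfg, seed)", {
  a <- small_study(seed = 17)
  b <- small_study(seed = 17)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$effects$effects, b$effects$effects)
  expect_identical(a$phenotypes$drp, b$phenotypes$drp)
  expect_identical(a$annotations$pathways$sets, b$annotations$pathways$sets)
})
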