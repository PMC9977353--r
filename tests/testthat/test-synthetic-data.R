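# synthetic-data generator: configuration contracts, genetic structure,
# run-confounded missingness, liability-threshold phenotypes

test_that("config validation names the offending field", {
  expect_error(sim_config(n_proteome = 500L), "n_proteome")
  expect_error(sim_config(allele_freq_range = c(0, 0.5)),
               "allele_freq_range")
  expect_error(sim_config(missing_protein_fraction_per_run = 1),
               "missing_protein_fraction_per_run")
  expect_error(sim_config(run_var = -1), "run_var")
  expect_error(trait_spec("x", h2 = 0.8, litter_prop = 0.4), "h2")
  expect_error(trait_spec("m", "binary", prevalence = NULL), "prevalence")
  # run slots: 150 proteome animals do not fit in 5 runs of 10
  expect_error(sim_config(n_runs_group1 = 3L, n_runs_group2 = 2L),
               "run slots")
})

test_that("population: HWE dosage means, litter nesting, determinism", {
  cfg <- sim_config(n_animals_total = 400L, n_proteome = 100L,
                    n_snps = 40L, allele_freq_range = c(0.5, 0.5),
                    n_runs_group1 = 5L, n_runs_group2 = 5L, seed = 7L)
  pop <- simulate_population(cfg)
  # mean dosage ~ 2p = 1; litter mates are full sibs (genotypic
  # correlation 0.5), so the binomial SE carries a design effect of
  # 1 + 0.5 (m - 1) with m the size-weighted mean litter size
  sizes <- table(pop$metadata$litter)
  deff <- 1 + 0.5 * (sum(sizes^2) / 400 - 1)
  se <- sqrt(2 * 0.5 * 0.5 / 400 * deff)
  expect_true(all(abs(colMeans(pop$genotypes) - 1) < 3.5 * se))
  expect_lt(abs(mean(colMeans(pop$genotypes)) - 1), 3 * se / sqrt(40))
  expect_true(all(pop$genotypes %in% 0:2))
  # one litter per animal; litters nest within company (and batch)
  md <- pop$metadata
  expect_false(anyNA(md$litter))
  nest <- tapply(as.character(md$company), md$litter,
                 function(x) length(unique(x)))
  expect_true(all(nest == 1))
  expect_equal(sum(md$has_proteome), 100L)
  # same seed twice: byte-identical
  pop2 <- simulate_population(cfg)
  expect_identical(pop, pop2)
})

test_that("litter mates are full sibs in the realized GRM", {
  d <- demo_fixture()
  G <- build_grm(d$genotypes)
  same <- outer(d$metadata$litter, d$metadata$litter, `==`) & upper.tri(G)
  expect_gt(mean(G[same]), 0.4)
  expect_lt(mean(G[same]), 0.6)
  expect_lt(abs(mean(G[!same & upper.tri(G)])), 0.05)
})

test_that("proteome: h2 = 0 gives a zero breeding-value component", {
  cfg <- sim_config(n_animals_total = 100L, n_proteome = 50L,
                    n_snps = 200L, n_proteins = 8L,
                    n_runs_group1 = 3L, n_runs_group2 = 2L,
                    protein_h2_distribution = list(name = "fixed",
                                                   value = 0),
                    seed = 3L)
  pop <- simulate_population(cfg)
  prot <- simulate_proteome(pop$genotypes, pop$metadata, cfg)
  expect_equal(max(abs(prot$truth$bv[, 1:8])), 0)
})

test_that("proteome: nuisance-free log2 abundances are i.i.d. normal", {
  cfg <- sim_config(n_animals_total = 300L, n_proteome = 150L,
                    n_snps = 200L, n_proteins = 100L,
                    n_runs_group1 = 8L, n_runs_group2 = 7L,
                    protein_h2_distribution = list(name = "fixed",
                                                   value = 0),
                    litter_var_proportion = 0, run_var = 0,
                    tag_effect_sd = 0, batch_effect_sd = 0,
                    entry_age_slope = 0, ref_slope = 0,
                    missing_protein_fraction_per_run = 0, seed = 5L)
  pop <- simulate_population(cfg)
  prot <- simulate_proteome(pop$genotypes, pop$metadata, cfg)
  lv <- log2(prot$abundance$values)
  pvals <- apply(lv, 2L, function(x) stats::shapiro.test(x)$p.value)
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("proteome: realized heritability matches the target", {
  # 1000 animals, all nuisance terms off: var(true BV) / var(log2) ~ h2
  cfg <- sim_config(n_animals_total = 1000L, n_proteome = 1000L,
                    n_snps = 600L, n_proteins = 4L,
                    n_runs_group1 = 50L, n_runs_group2 = 50L,
                    n_batches = 10L,
                    protein_h2_distribution = list(name = "fixed",
                                                   value = 0.5),
                    litter_var_proportion = 0.1, run_var = 0,
                    tag_effect_sd = 0, batch_effect_sd = 0,
                    entry_age_slope = 0, ref_slope = 0,
                    missing_protein_fraction_per_run = 0, seed = 13L)
  pop <- simulate_population(cfg)
  prot <- simulate_proteome(pop$genotypes, pop$metadata, cfg)
  lv <- log2(prot$abundance$values)
  an <- prot$plate_map$animal_id
  h2_real <- vapply(1:4, function(j)
    stats::var(prot$truth$bv[an, j]) / stats::var(lv[, j]), numeric(1))
  expect_true(all(abs(h2_real - 0.5) < 0.05))
})

test_that("missingness: all-or-none per protein x run, independent of level", {
  cfg <- sim_config(n_animals_total = 600L, n_proteome = 500L,
                    n_snps = 200L, n_proteins = 400L,
                    n_runs_group1 = 25L, n_runs_group2 = 25L,
                    n_batches = 10L,
                    missing_protein_fraction_per_run = 0.2, seed = 17L)
  pop <- simulate_population(cfg)
  prot <- simulate_proteome(pop$genotypes, pop$metadata, cfg)
  ab <- inject_missingness_by_run(prot$abundance, prot$plate_map, cfg)
  runs <- prot$plate_map$run[match(rownames(ab$values),
                                   prot$plate_map$sample_id)]
  for (r in levels(runs)) {
    rows <- which(runs == r)
    miss <- colSums(is.na(ab$values[rows, , drop = FALSE]))
    expect_true(all(miss %in% c(0L, length(rows))))
  }
  # independence of abundance level: |cor| < 0.1 at 50 runs x 200 proteins
  rep <- missingness_report(ab, prot$plate_map)
  expect_lt(abs(attr(rep, "cor_missing_abundance")), 0.1)
  # fraction = 0 leaves nothing missing
  cfg0 <- sim_config(seed = 2L, missing_protein_fraction_per_run = 0)
  pop0 <- simulate_population(cfg0)
  pr0 <- simulate_proteome(pop0$genotypes, pop0$metadata, cfg0)
  ab0 <- inject_missingness_by_run(pr0$abundance, pr0$plate_map, cfg0)
  expect_false(anyNA(ab0$values))
})

test_that("phenotypes: prevalence, null rg, and survivor masking", {
  cfg <- sim_config(
    n_animals_total = 2000L, n_proteome = 100L, n_snps = 300L,
    n_proteins = 5L, n_runs_group1 = 5L, n_runs_group2 = 5L,
    n_batches = 10L,
    trait_specs = list(
      trait_spec("MOR", "binary", "finisher", h2 = 0.1, prevalence = 0.5,
                 lower_is_better = TRUE),
      trait_spec("ADG", "continuous", "finisher", h2 = 0.3),
      trait_spec("HS", "score", "challenge_nursery", h2 = 0.15)),
    seed = 23L)
  pop <- simulate_population(cfg)
  ph <- simulate_phenotypes(pop$genotypes, pop$metadata, cfg)
  prev <- mean(ph$phenotypes$MOR)
  expect_lt(abs(prev - 0.5), 3 * sqrt(0.25 / 2000))
  # no planted rg: trait BVs uncorrelated with protein BVs. Full-sib
  # litters (~8) cut the effective n to ~450, so 3 SE ~ 0.14
  prot <- simulate_proteome(pop$genotypes, pop$metadata, cfg)
  cc <- cor(ph$truth$bv_traits[, "ADG"], prot$truth$bv[, 1:5])
  expect_true(all(abs(cc) < 0.15))
  # survivor variant masks finisher records of deaths, expanded keeps them
  died <- ph$truth$died
  expect_true(all(is.na(ph$phenotypes$ADG[died])))
  expect_false(anyNA(ph$phenotypes_expanded$ADG))
  expect_true(all(ph$phenotypes$HS %in% 1:5))
})

test_that("planted genetic correlation is realized in true breeding values", {
  cfg <- sim_config(
    n_animals_total = 2000L, n_proteome = 100L, n_snps = 300L,
    n_proteins = 3L, n_runs_group1 = 5L, n_runs_group2 = 5L,
    n_batches = 10L,
    protein_h2_distribution = list(name = "fixed", value = 0.4),
    trait_specs = list(trait_spec("T", "continuous", "finisher", h2 = 0.3,
                                  rg_with_proteins = c(-0.6))),
    seed = 29L)
  pop <- simulate_population(cfg)
  prot <- simulate_proteome(pop$genotypes, pop$metadata, cfg)
  ph <- simulate_phenotypes(pop$genotypes, pop$metadata, cfg)
  r <- cor(prot$truth$bv[, "PROT001"], ph$truth$bv_traits[, "T"])
  # 3 SE of a correlation of -0.6 at the litter-adjusted effective n
  expect_lt(abs(r - (-0.6)), 0.1)
  # proteome and phenotype calls share one joint breeding-value draw
  expect_identical(prot$truth$bv[, "T"], ph$truth$bv_traits[, "T"])
})

test_that("infeasible rg matrix errors and names the offending pair", {
  cfg <- sim_config(
    n_proteins = 2L, n_animals_total = 60L, n_proteome = 40L,
    n_snps = 100L, n_runs_group1 = 2L, n_runs_group2 = 2L,
    trait_specs = list(
      trait_spec("T1", "continuous", "finisher", h2 = 0.3,
                 rg_with_proteins = c(0.99)),
      trait_spec("T2", "continuous", "finisher", h2 = 0.3,
                 rg_with_proteins = c(0.99)),
      trait_spec("T3", "continuous", "finisher", h2 = 0.3,
                 rg_with_proteins = c(-0.99))),
    seed = 31L)
  pop <- simulate_population(cfg)
  expect_error(simulate_phenotypes(pop$genotypes, pop$metadata, cfg),
               "positive semi-definite")
})

test_that("generate_dataset writes the documented TSV/JSON files", {
  out <- withr::local_tempdir()
  cfg <- sim_config(n_animals_total = 80L, n_proteome = 40L, n_snps = 60L,
                    n_proteins = 6L, n_runs_group1 = 2L,
                    n_runs_group2 = 2L, n_batches = 2L, seed = 41L)
  generate_dataset(cfg, out_dir = out)
  for (f in c("genotypes.tsv", "metadata.tsv", "plate_map.tsv",
              "abundance_raw.tsv", "reference.tsv",
              "phenotypes_survivor.tsv", "phenotypes_expanded.tsv",
              "trait_info.tsv", "truth.json", "schema.json"))
    expect_true(file.exists(file.path(out, f)), label = f)
  tr <- jsonlite::read_json(file.path(out, "truth.json"),
                            simplifyVector = TRUE)
  expect_length(tr$protein_h2, 6L)
})
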