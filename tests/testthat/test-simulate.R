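# synthetic_data: parental populations, hybrid founding, clonal evolution,
# backcrossing, dataset assembly

test_that("parental simulation respects frequencies and determinism", {
  loci <- sim_loci(2)
  mono <- setNames(lapply(loci$name, function(l) c(`120` = 1.0)), loci$name)
  ds <- simulate_parental_population(mono, 5, loci, seed = 1)
  expect_true(all(ds$geno$L01.1 == 120L & ds$geno$L01.2 == 120L))
  # frequency recovery at n = 1000
  spec <- setNames(lapply(loci$name, function(l) c(`120` = 0.3, `124` = 0.7)),
                   loci$name)
  big <- simulate_parental_population(spec, 1000, loci, seed = 2)
  obs <- allele_frequencies(big)[[1]]$freqs$L01[["120"]]
  expect_lt(abs(obs - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
  # same seed, identical sample
  again <- simulate_parental_population(spec, 1000, loci, seed = 2)
  expect_identical(big$geno, again$geno)
})

test_that("hybrid founders are heterozygous with disjoint parental pools", {
  loci <- sim_loci(6)
  mf <- draw_parental_freqs(loci, offset = 0, seed = 3)
  pf <- draw_parental_freqs(loci, offset = 10, seed = 4)
  mds <- simulate_parental_population(mf, 20, loci, "m", seed = 3)
  pds <- simulate_parental_population(pf, 20, loci, "p", seed = 4)
  f <- form_hybrid(mds, pds, seed = 5)
  expect_true(all(f$calls["maternal", ] != f$calls["paternal", ]))
  for (l in loci$name) {
    expect_true(as.character(f$calls["maternal", l]) %in% names(mf[[l]]))
    expect_true(as.character(f$calls["paternal", l]) %in% names(pf[[l]]))
  }
})

test_that("Monte-Carlo formation frequency matches the analytic model", {
  loci <- sim_loci(2)
  mf <- draw_parental_freqs(loci, n_alleles = 3, offset = 0, seed = 6)
  pf <- draw_parental_freqs(loci, n_alleles = 3, offset = 10, seed = 7)
  mds <- simulate_parental_population(mf, 60, loci, "m", seed = 6)
  pds <- simulate_parental_population(pf, 60, loci, "p", seed = 7)
  fm <- allele_frequencies(mds)[["m"]]
  fp <- allele_frequencies(pds)[["p"]]
  # target: most common allele from each pool at each locus
  gt <- multilocus_genotype(setNames(lapply(loci$name, function(l) {
    c(as.integer(names(which.max(fm$freqs[[l]]))),
      as.integer(names(which.max(fp$freqs[[l]]))))
  }), loci$name))
  want <- hybrid_formation_prob(gt, fp, fm, "random_union")$prob
  mc <- hybrid_formation_mc(gt, mds, pds, n_draws = 2e4, seed = 8)
  se <- sqrt(want * (1 - want) / mc$n_draws)
  expect_lt(abs(mc$estimate - want), 3 * se)
})

test_that("clonal evolution is inert at zero rates and replayable", {
  loci <- sim_loci(4)
  f <- structure(list(
    calls = rbind(maternal = setNames(c(120, 122, 124, 126), loci$name),
                  paternal = setNames(c(160, 162, 164, 166), loci$name)),
    loci = loci), class = "sim_founder")
  still <- evolve_clonal_lineage(f, n = 5, G = 30, mu = 0, conv = 0, seed = 9)
  for (st in still$states) expect_identical(st, f$calls)
  expect_equal(nrow(still$events), 0L)
  active <- evolve_clonal_lineage(f, n = 8, G = 25, mu = 0.05, conv = 0.05,
                                  seed = 10)
  expect_gt(nrow(active$events), 0L)
  replayed <- msatclones:::replay_lineage(f, 8, active$events)
  expect_identical(replayed, active$states)
})

test_that("heterozygosity decays as h0 (1 - c)^G under pure conversion", {
  loci <- sim_loci(10)
  f <- structure(list(
    calls = rbind(maternal = setNames(seq(120, by = 10, length.out = 10),
                                      loci$name),
                  paternal = setNames(seq(125, by = 10, length.out = 10),
                                      loci$name)),
    loci = loci), class = "sim_founder")
  G <- 12; cc <- 0.05; n <- 400
  lin <- evolve_clonal_lineage(f, n = n, G = G, mu = 0, conv = cc, seed = 11)
  p_exp <- (1 - cc)^G  # founder fully heterozygous, h0 = 1
  het <- vapply(lin$states, function(st) mean(st[1, ] != st[2, ]), numeric(1))
  se <- sqrt(p_exp * (1 - p_exp) / (n * 10))
  expect_lt(abs(mean(het) - p_exp), 3 * se)
})

test_that("conversion raises homozygosity monotonically in G", {
  loci <- sim_loci(8)
  f <- structure(list(
    calls = rbind(maternal = setNames(seq(120, by = 10, length.out = 8),
                                      loci$name),
                  paternal = setNames(seq(125, by = 10, length.out = 8),
                                      loci$name)),
    loci = loci), class = "sim_founder")
  hoz <- vapply(c(0, 5, 15, 40), function(G) {
    lin <- evolve_clonal_lineage(f, n = 150, G = G, mu = 0, conv = 0.04,
                                 seed = 12)
    mean(vapply(lin$states, function(st) mean(st[1, ] == st[2, ]), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(hoz) > 0))
})

test_that("backcross replaces paternal alleles as configured", {
  loci <- sim_loci(10)
  f <- structure(list(
    calls = rbind(maternal = setNames(seq(120, by = 10, length.out = 10),
                                      loci$name),
                  paternal = setNames(seq(125, by = 10, length.out = 10),
                                      loci$name)),
    loci = loci), class = "sim_founder")
  donor_spec <- setNames(lapply(seq_len(10), function(i)
    setNames(1.0, 500 + 10 * i)), loci$name)
  donor <- simulate_parental_population(donor_spec, 10, loci, "d", seed = 13)
  none <- backcross(f, donor, 0, seed = 14)
  expect_identical(none$founder$calls, f$calls)
  all_r <- backcross(f, donor, 1, seed = 14)
  expect_true(all(all_r$replaced))
  expect_equal(unname(all_r$founder$calls["paternal", ]),
               500 + 10 * seq_len(10))
  expect_identical(all_r$founder$calls["maternal", ], f$calls["maternal", ])
})

test_that("backcrossed sister lineages keep unreplaced loci identical", {
  loci <- sim_loci(10)
  mf <- draw_parental_freqs(loci, offset = 0, seed = 15)
  pf <- draw_parental_freqs(loci, offset = 10, seed = 16)
  mds <- simulate_parental_population(mf, 20, loci, "m", seed = 15)
  pds <- simulate_parental_population(pf, 20, loci, "p", seed = 16)
  f1 <- form_hybrid(mds, pds, seed = 17)
  bc <- backcross(f1, pds, 0.3, seed = 18)
  lin1 <- evolve_clonal_lineage(f1, 10, G = 0, species = "s1", seed = 19)
  lin2 <- evolve_clonal_lineage(bc$founder, 10, G = 0, species = "s2", seed = 20)
  ds <- sample_dataset(list(lin1$dataset, lin2$dataset), missing_rate = 0,
                       seed = 21)
  res <- max_shared_loci(ds, "s1", "s2")
  # loci the backcross did not touch (and where the donor gamete allele
  # did not coincide) remain identical between the lineages
  changed <- bc$founder$calls["paternal", ] != f1$calls["paternal", ]
  expect_equal(res$max, 10L - sum(changed))
})

test_that("dataset assembly hits the target missing rate and validates", {
  sc_groups <- list(random_dataset(n = 150, seed = 22),
                    {
                      d <- random_dataset(n = 139, seed = 23)
                      d$geno$species <- "rand2"
                      d$geno$id <- paste0("r2_", seq_len(nrow(d$geno)))
                      d
                    })
  ds <- sample_dataset(sc_groups, missing_rate = 0.124, seed = 24)
  obs <- missing_rate(ds)
  # per-individual cap truncation pulls the expectation slightly below the
  # nominal per-call rate; binomial 3 SE still covers it at 289 x 5 calls
  se <- sqrt(0.124 * 0.876 / (289 * 5))
  expect_lt(abs(obs - 0.124), 3 * se + 0.01)
  complete <- sample_dataset(sc_groups, missing_rate = 0, seed = 24)
  expect_equal(missing_rate(complete), 0)
  # determinism: identical bytes on re-run
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(sample_dataset(sc_groups, 0.124, seed = 25), p1)
  write_genotype_table(sample_dataset(sc_groups, 0.124, seed = 25), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("community simulation reproduces the study-panel shape", {
  com <- simulate_community(seed = 30)
  ds <- com$dataset
  expect_equal(length(unique(ds$geno$species)), 13L)  # 7 + 4 + 2
  expect_equal(nrow(ds$loci), 10L)
  expect_equal(nrow(ds$geno), sum(c(44, 29, 27, 17, 19, 14, 15),
                                  c(42, 30, 25, 20), c(35, 40)))
  expect_lt(abs(missing_rate(ds) - 0.124), 0.02)
  # parthenogens carry heterozygote excess; sister pairs share genotypes
  h <- heterozygosity(ds, "partheno1")
  expect_gt(h$het_excess, 0)
  m67 <- max_shared_loci(ds, "partheno6", "partheno7")
  m35 <- max_shared_loci(ds, "partheno3", "partheno5")
  expect_gt(m67$max, m35$max)
})

test_that("scenario truth records origins and replays", {
  sc <- simulate_scenario("single_origin", n_parthenogens = 3,
                          backcross_prob = 0.3, missing_rate = 0.05, seed = 26)
  expect_equal(sc$truth$origin[1], "founder1")
  expect_true(all(grepl("backcross", sc$truth$origin[2:3])))
  expect_setequal(unique(sc$dataset$geno$species),
                  c("maternal", "paternal", "partheno1", "partheno2",
                    "partheno3"))
  sc_ind <- simulate_scenario("independent_origin", seed = 27)
  expect_equal(sc_ind$truth$origin, c("founder1", "founder2"))
  # same seed reproduces the dataset exactly
  sc2 <- simulate_scenario("independent_origin", seed = 27)
  expect_identical(sc2$dataset$geno, sc_ind$dataset$geno)
})
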