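# shared_genotypes: shared alleles, k-locus genotypes, discovery

test_that("pairwise shared-allele proportion counts multiset overlap", {
  loci <- loci2()
  ds <- toy_dataset(list(
    ind("a", "g1", LA = c(150, 154), LB = c(200, 204)),
    ind("b", "g2", LA = c(150, 158), LB = c(200, 204)),
    ind("c", "g2", LA = c(150, 154), LB = c(200, 204))), loci)
  expect_equal(prop_shared_alleles(ds, "a", "c"), 1.0)
  expect_equal(prop_shared_alleles(ds, "a", "b"), (0.5 + 1.0) / 2)
  # homozygote vs heterozygote: 150/150 vs 150/154 shares one of two
  ds2 <- toy_dataset(list(
    ind("a", "g1", LA = c(150, 150), LB = c(200, 200)),
    ind("b", "g2", LA = c(150, 154), LB = c(200, 200))), loci)
  expect_equal(prop_shared_alleles(ds2, "a", "b"), (0.5 + 1.0) / 2)
})

test_that("group mean equals exhaustive pair enumeration on a toy", {
  loci <- loci2()
  ds <- toy_dataset(list(
    ind("a1", "g1", LA = c(150, 154), LB = c(200, 204)),
    ind("a2", "g1", LA = c(150, 150), LB = c(204, 204)),
    ind("b1", "g2", LA = c(150, 158), LB = c(200, 204)),
    ind("b2", "g2", LA = c(154, 158), LB = c(208, 212))), loci)
  want <- mean(c(prop_shared_alleles(ds, "a1", "b1"),
                 prop_shared_alleles(ds, "a1", "b2"),
                 prop_shared_alleles(ds, "a2", "b1"),
                 prop_shared_alleles(ds, "a2", "b2")))
  expect_equal(group_shared_alleles(ds, "g1", "g2"), want)
  expect_equal(group_shared_alleles(ds, "g2", "g1"), want)  # symmetric
})

test_that("k-locus genotype proportion: clones are 1, disjoint pools are 0", {
  loci <- loci2()
  clone <- list(LA = c(150, 154), LB = c(200, 204))
  ds <- toy_dataset(list(
    c(list(id = "a", species = "g1"), list(calls = clone)),
    c(list(id = "b", species = "g2"), list(calls = clone))), loci)
  for (k in 1:2) {
    expect_equal(shared_klocus_genotype_proportion(ds, "g1", "g2", k), 1.0)
  }
  ds0 <- toy_dataset(list(
    ind("a", "g1", LA = c(150, 154), LB = c(200, 204)),
    ind("b", "g2", LA = c(158, 162), LB = c(208, 212))), loci)
  expect_equal(shared_klocus_genotype_proportion(ds0, "g1", "g2", 1), 0)
})

test_that("k = 1 proportion equals brute-force genotype matching", {
  loci <- loci2()
  ds <- toy_dataset(list(
    ind("a1", "g1", LA = c(150, 154), LB = c(200, 204)),
    ind("a2", "g1", LA = c(150, 154), LB = c(204, 204)),
    ind("b1", "g2", LA = c(150, 154), LB = c(200, 204)),
    ind("b2", "g2", LA = c(150, 158), LB = c(204, 204))), loci)
  # oracle: per locus, fraction of cross pairs with identical diploid
  # genotype, averaged over the 2 loci
  gA <- list(LA = c("150/154", "150/154"), LB = c("200/204", "204/204"))
  gB <- list(LA = c("150/154", "150/158"), LB = c("200/204", "204/204"))
  want <- mean(c(mean(outer(gA$LA, gB$LA, `==`)),
                 mean(outer(gA$LB, gB$LB, `==`))))
  expect_equal(shared_klocus_genotype_proportion(ds, "g1", "g2", 1), want)
})

test_that("k = 2 is never larger than k = 1 (joint identity is stricter)", {
  for (seed in 1:3) {
    sc <- simulate_scenario("independent_origin", mu = 0.02, conv = 0.02,
                            missing_rate = 0.1, seed = seed)
    k1 <- shared_klocus_genotype_proportion(sc$dataset, "partheno1",
                                            "partheno2", 1)
    k2 <- shared_klocus_genotype_proportion(sc$dataset, "partheno1",
                                            "partheno2", 2)
    expect_lte(k2, k1 + 1e-12)
  }
})

test_that("max shared loci is symmetric and counts identical diploid calls", {
  loci <- sim_loci(10)
  calls <- setNames(lapply(1:10, function(i) c(120L, 124L)), loci$name)
  callsB <- calls
  for (l in loci$name[1:7]) callsB[[l]] <- c(130L, 134L)  # 3 conserved
  ds <- toy_dataset(list(
    c(list(id = "a", species = "g1"), list(calls = calls)),
    c(list(id = "b", species = "g2"), list(calls = callsB)),
    c(list(id = "c", species = "g2"), list(calls = calls))), loci)
  res <- max_shared_loci(ds, "g1", "g2")
  expect_equal(res$max, 10L)
  expect_equal(unname(res$pair_matrix["a", "b"]), 3L)
  res_rev <- max_shared_loci(ds, "g2", "g1")
  expect_equal(res_rev$max, res$max)
  expect_equal(t(res_rev$pair_matrix), res$pair_matrix)
})

test_that("two groups fixed for one heterozygous 3-locus genotype are reported", {
  loci <- locus_table(c("Du183", "Du47", "Du323"), motif_length = 4L)
  clone <- list(Du183 = c(189, 193), Du47 = c(278, 286), Du323 = c(185, 213))
  rows <- c(
    lapply(1:4, function(i) c(list(id = paste0("a", i), species = "g1"),
                              list(calls = clone))),
    lapply(1:4, function(i) c(list(id = paste0("b", i), species = "g2"),
                              list(calls = clone))))
  ds <- toy_dataset(rows, loci)
  rep <- find_shared_multilocus_genotypes(ds, max_loci = 3)
  expect_equal(nrow(rep), 1L)  # maximal subset only
  expect_equal(rep$n_loci, 3L)
  expect_equal(rep$freqs, "1,1")
  expect_equal(rep$zygosity, "het,het,het")
})

test_that("carrier frequencies reproduce a two-group fixture exactly", {
  # 31 carriers-of-32 in one species, 28-of-32 in the other, one shared
  # 3-locus heterozygous genotype; frequencies must be carrier/scored
  loci <- locus_table(c("Du183", "Du47", "Du323"), motif_length = 4L)
  clone <- list(Du183 = c(189, 193), Du47 = c(278, 286), Du323 = c(185, 213))
  other <- list(Du183 = c(201, 205), Du47 = c(290, 294), Du323 = c(221, 225))
  mk <- function(sp, n_carr, n_tot) {
    lapply(seq_len(n_tot), function(i) {
      c(list(id = sprintf("%s%02d", sp, i), species = sp),
        list(calls = if (i <= n_carr) clone else other))
    })
  }
  ds <- toy_dataset(c(mk("g1", 21, 31), mk("g2", 28, 32)), loci)
  rep <- find_shared_multilocus_genotypes(ds, max_loci = 3)
  shared3 <- rep[rep$n_loci == 3 & rep$combined_freq > 1, ]
  expect_equal(nrow(shared3), 1L)
  f <- as.numeric(strsplit(shared3$freqs, ",")[[1]])
  expect_equal(f, c(21 / 31, 28 / 32), tolerance = 1e-6)
  expect_equal(round(f[1], 3), 0.677)
  expect_equal(f[2], 0.875)
})

test_that("discovery equals brute-force enumeration on a 4-locus toy", {
  loci <- locus_table(paste0("L", 1:4), motif_length = 2L)
  set.seed(31)
  mkcalls <- function() setNames(lapply(1:4, function(i)
    sort(sample(c(100L, 102L, 104L), 2, replace = TRUE))), loci$name)
  rows <- c(
    lapply(1:5, function(i) c(list(id = paste0("a", i), species = "g1"),
                              list(calls = mkcalls()))),
    lapply(1:5, function(i) c(list(id = paste0("b", i), species = "g2"),
                              list(calls = mkcalls()))))
  ds <- toy_dataset(rows, loci)
  rep <- find_shared_multilocus_genotypes(ds, min_freq = 0.05, max_loci = 4)
  # oracle: check every reported row by direct counting, and that every
  # single-locus shared genotype appears in some report row (possibly as
  # part of a maximal superset)
  keymat <- sapply(loci$name, function(l) {
    paste0(ds$geno[[paste0(l, ".1")]], "/", ds$geno[[paste0(l, ".2")]])
  })
  rownames(keymat) <- ds$geno$id
  for (i in seq_len(nrow(rep))) {
    lset <- strsplit(rep$loci[i], ",")[[1]]
    gcalls <- sub("^.*=", "", strsplit(rep$genotype[i], ";")[[1]])
    for (grp_i in seq_along(strsplit(rep$groups[i], ",")[[1]])) {
      grp <- strsplit(rep$groups[i], ",")[[1]][grp_i]
      sel <- ds$geno$species == grp
      carriers <- apply(keymat[sel, lset, drop = FALSE], 1, function(r)
        all(r == gcalls))
      f_direct <- mean(carriers)
      f_rep <- as.numeric(strsplit(rep$freqs[i], ",")[[1]])[grp_i]
      expect_equal(f_rep, f_direct, tolerance = 1e-9)
    }
  }
  # every cross-group single-locus match is covered by some report
  for (l in loci$name) {
    shared <- intersect(keymat[1:5, l], keymat[6:10, l])
    for (gt in shared) {
      covered <- any(vapply(seq_len(nrow(rep)), function(i) {
        lset <- strsplit(rep$loci[i], ",")[[1]]
        gcalls <- sub("^.*=", "", strsplit(rep$genotype[i], ";")[[1]])
        l %in% lset && gcalls[match(l, lset)] == gt
      }, logical(1)))
      expect_true(covered, label = sprintf("locus %s genotype %s covered", l, gt))
    }
  }
})
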