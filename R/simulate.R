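# Forward simulator: bisexual parental populations in HWE, hybrid origin,
# clonal propagation under stepwise mutation and allelic conversion (loss
# of heterozygosity), optional backcross enrichment. Every stochastic
# operation takes an explicit integer seed and uses R's Mersenne-Twister,
# so identical configs reproduce byte-identical datasets.
#
# Internal genotype state keeps allele order meaningful: slot 1 holds the
# maternally derived allele and slot 2 the paternally derived one;
# canonicalization to unordered pairs happens only on export.

#' Default locus panel for simulations
#'
#' Ten loci with di- and tetranucleotide motifs, emulating a typical STR
#' panel.
#'
#' @param n_loci number of loci (default 10).
#' @return a [locus_table()].
#' @export
sim_loci <- function(n_loci = 10L) {
  locus_table(sprintf("L%02d", seq_len(n_loci)),
              motif_length = rep_len(c(2L, 4L), n_loci))
}

#' Draw per-population allele frequency vectors
#'
#' Allele sizes sit on the locus ladder (`base + motif * k`); frequencies
#' are drawn from a symmetric Dirichlet (gamma-normalized) with the given
#' concentration. Distinct `offset` values give populations
#' non-overlapping allele pools, the idealized signature of divergent
#' parental species.
#'
#' @param loci a [locus_table()].
#' @param n_alleles alleles per locus.
#' @param concentration symmetric Dirichlet concentration (default 1).
#' @param offset ladder offset in repeat units separating this population's
#'   allele range from others.
#' @param base_size smallest allele size in bp before the offset.
#' @param seed integer seed.
#' @return named list: locus -> named numeric frequency vector.
#' @export
draw_parental_freqs <- function(loci, n_alleles = 5L, concentration = 1,
                                offset = 0L, base_size = 120L, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(loci))) {
    sizes <- base_size + loci$motif_length[i] *
      (offset + seq_len(n_alleles) - 1L)
    w <- stats::rgamma(n_alleles, shape = concentration)
    out[[loci$name[i]]] <- stats::setNames(w / sum(w), sizes)
  }
  out
}

#' Simulate a bisexual parental population in HWE
#'
#' Each gene copy is drawn independently from the population's allele
#' frequencies, so genotype frequencies follow Hardy-Weinberg proportions.
#'
#' @param freq_spec named list: locus -> named frequency vector summing
#'   to 1.
#' @param n number of diploid individuals.
#' @param loci a [locus_table()] covering the spec.
#' @param species,population labels for the emitted individuals.
#' @param seed integer seed.
#' @return a [genotype_dataset()].
#' @export
simulate_parental_population <- function(freq_spec, n, loci,
                                         species = "parental",
                                         population = species, seed = 1L) {
  set.seed(seed)
  for (l in names(freq_spec)) {
    if (abs(sum(freq_spec[[l]]) - 1) > 1e-9) {
      stop("frequencies at locus ", l, " do not sum to 1")
    }
  }
  df <- data.frame(id = sprintf("%s_%03d", species, seq_len(n)),
                   species = species, population = population,
                   stringsAsFactors = FALSE)
  for (l in loci$name) {
    f <- freq_spec[[l]]
    sizes <- as.integer(names(f))
    a1 <- sizes[sample.int(length(sizes), n, replace = TRUE, prob = f)]
    a2 <- sizes[sample.int(length(sizes), n, replace = TRUE, prob = f)]
    df[[paste0(l, ".1")]] <- pmin(a1, a2)
    df[[paste0(l, ".2")]] <- pmax(a1, a2)
  }
  genotype_dataset(df, loci = loci)
}

# random gamete (one allele per locus) from a random individual of a group
draw_gamete <- function(dataset) {
  i <- sample(nrow(dataset$geno), 1L)
  a1 <- allele_matrix(dataset, 1L)[i, ]
  a2 <- allele_matrix(dataset, 2L)[i, ]
  pick <- stats::runif(length(a1)) < 0.5
  stats::setNames(ifelse(pick, a1, a2), names(a1))
}

#' Found a hybrid clone
#'
#' Draws one random gamete from a random individual of the maternal group
#' and one from the paternal group; the union is the founding clonal
#' genotype, with parental origin of each allele recorded.
#'
#' @param maternal_group,paternal_group [genotype_dataset()] objects on the
#'   same loci.
#' @param seed integer seed.
#' @return a `sim_founder`: list with `calls` (2 x L matrix; row
#'   "maternal", row "paternal", columns loci, allele sizes in bp) and
#'   `loci`.
#' @export
form_hybrid <- function(maternal_group, paternal_group, seed = 1L) {
  set.seed(seed)
  gm <- draw_gamete(maternal_group)
  gp <- draw_gamete(paternal_group)
  calls <- rbind(maternal = gm, paternal = gp)
  structure(list(calls = calls, loci = maternal_group$loci),
            class = "sim_founder")
}

#' Evolve a clonal lineage from a founder
#'
#' Samples `n` individuals, each evolved independently for `G` generations
#' from the founding genotype (a star genealogy). Per generation and locus,
#' independently: with probability `mu` one randomly chosen allele steps
#' one repeat unit up or down (stepwise mutation model); with probability
#' `conv` a heterozygous locus loses heterozygosity, becoming homozygous
#' for one of its two alleles (the paternally derived one with probability
#' `conversion_bias`) — conversion of an already homozygous locus is a
#' no-op. All events are logged so a run can be replayed exactly.
#'
#' @param founder a `sim_founder` from [form_hybrid()] or [backcross()].
#' @param n sampled individuals.
#' @param G generations of clonal propagation.
#' @param mu per-locus per-generation stepwise mutation rate.
#' @param conv per-locus per-generation conversion (LOH) rate.
#' @param conversion_bias probability that conversion keeps the paternal
#'   allele (0.5 = unbiased).
#' @param species,population labels for the emitted individuals.
#' @param seed integer seed.
#' @return list with `dataset` (a [genotype_dataset()]), `states` (list of
#'   2 x L matrices, maternal/paternal rows), and `events` (data.frame:
#'   individual, generation, locus, event, slot, detail).
#' @export
evolve_clonal_lineage <- function(founder, n, G, mu = 0, conv = 0,
                                  conversion_bias = 0.5,
                                  species = "clone", population = species,
                                  seed = 1L) {
  stopifnot(mu >= 0, mu <= 1, conv >= 0, conv <= 1, G >= 0)
  set.seed(seed)
  loci <- founder$loci
  L <- nrow(loci)
  events <- list()
  states <- vector("list", n)
  for (ind in seq_len(n)) {
    st <- founder$calls
    if (G > 0) for (g in seq_len(G)) {
      for (k in seq_len(L)) {
        if (stats::runif(1) < mu) {
          slot <- sample(2L, 1L)
          delta <- sample(c(-1L, 1L), 1L)
          st[slot, k] <- st[slot, k] + delta * loci$motif_length[k]
          events[[length(events) + 1L]] <- data.frame(
            individual = ind, generation = g, locus = loci$name[k],
            event = "mutation", slot = slot, detail = delta)
        }
        if (st[1, k] != st[2, k] && stats::runif(1) < conv) {
          keep <- if (stats::runif(1) < conversion_bias) 2L else 1L
          st[, k] <- st[keep, k]
          events[[length(events) + 1L]] <- data.frame(
            individual = ind, generation = g, locus = loci$name[k],
            event = "conversion", slot = keep, detail = 0L)
        }
      }
    }
    states[[ind]] <- st
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(individual = integer(0), generation = integer(0),
               locus = character(0), event = character(0),
               slot = integer(0), detail = integer(0))
  list(dataset = states_to_dataset(states, loci, species, population),
       states = states, events = events)
}

# Replays an event log from a founder; must reproduce `states` exactly.
replay_lineage <- function(founder, n, events) {
  loci <- founder$loci
  states <- rep(list(founder$calls), n)
  if (nrow(events)) for (r in seq_len(nrow(events))) {
    e <- events[r, ]
    k <- match(e$locus, loci$name)
    if (e$event == "mutation") {
      states[[e$individual]][e$slot, k] <-
        states[[e$individual]][e$slot, k] + e$detail * loci$motif_length[k]
    } else {
      states[[e$individual]][, k] <- states[[e$individual]][e$slot, k]
    }
  }
  states
}

states_to_dataset <- function(states, loci, species, population) {
  df <- data.frame(id = sprintf("%s_%03d", species, seq_along(states)),
                   species = species, population = population,
                   stringsAsFactors = FALSE)
  for (k in seq_len(nrow(loci))) {
    a1 <- vapply(states, function(s) s[1, k], numeric(1))
    a2 <- vapply(states, function(s) s[2, k], numeric(1))
    df[[paste0(loci$name[k], ".1")]] <- as.integer(pmin(a1, a2))
    df[[paste0(loci$name[k], ".2")]] <- as.integer(pmax(a1, a2))
  }
  genotype_dataset(df, loci = loci)
}

#' Backcross a clonal genotype with a bisexual donor
#'
#' Models re-seeding of a new clonal lineage after a backcross: per locus,
#' with probability `replace_prob`, the paternally derived allele is
#' replaced by a random gamete allele from the donor group. The result is
#' a new founder that is identical to the source lineage at unreplaced
#' loci — the divergent-but-partially-identical pattern expected between
#' sister parthenogens.
#'
#' @param founder a `sim_founder`.
#' @param donor_group a [genotype_dataset()] on the same loci.
#' @param replace_prob per-locus replacement probability.
#' @param seed integer seed.
#' @return list with `founder` (new `sim_founder`) and `replaced` (logical
#'   per-locus vector).
#' @export
backcross <- function(founder, donor_group, replace_prob, seed = 1L) {
  stopifnot(replace_prob >= 0, replace_prob <= 1)
  set.seed(seed)
  gd <- draw_gamete(donor_group)
  replaced <- stats::runif(ncol(founder$calls)) < replace_prob
  calls <- founder$calls
  calls["paternal", replaced] <- gd[replaced]
  list(founder = structure(list(calls = calls, loci = founder$loci),
                           class = "sim_founder"),
       replaced = stats::setNames(replaced, colnames(calls)))
}

#' Monte-Carlo estimate of a hybrid formation probability
#'
#' Draws `n_draws` independent hybridization events (one random gamete from
#' a random individual of each parental group) and reports the fraction
#' producing the target unordered genotype at its loci. Estimates the
#' random-union formation probability, i.e. [hybrid_formation_prob()] with
#' `hom_mode = "random_union"` evaluated at the parental groups' empirical
#' allele frequencies.
#'
#' Gametes are drawn per locus from the individuals scored at that locus,
#' matching the conditioning of [allele_frequencies()] when calls are
#' missing; for unlinked loci this is distributionally equivalent to
#' whole-individual gamete draws.
#'
#' @param genotype a [multilocus_genotype()].
#' @param maternal_group,paternal_group [genotype_dataset()] objects.
#' @param n_draws number of simulated hybridizations.
#' @param seed integer seed.
#' @return list with `estimate`, `se` (binomial standard error), `n_draws`.
#' @export
hybrid_formation_mc <- function(genotype, maternal_group, paternal_group,
                                n_draws = 1e5, seed = 1L) {
  set.seed(seed)
  draw <- function(ds) {
    a1 <- allele_matrix(ds, 1L)
    a2 <- allele_matrix(ds, 2L)
    g <- matrix(0L, n_draws, length(names(genotype)),
                dimnames = list(NULL, names(genotype)))
    for (l in names(genotype)) {
      scored <- which(!is.na(a1[, l]))
      if (length(scored) == 0L) stop("no scored individuals at locus ", l)
      idx <- scored[sample.int(length(scored), n_draws, replace = TRUE)]
      pick <- stats::runif(n_draws) < 0.5
      g[, l] <- ifelse(pick, a1[idx, l], a2[idx, l])
    }
    g
  }
  gm <- draw(maternal_group)
  gp <- draw(paternal_group)
  ok <- rep(TRUE, n_draws)
  for (l in names(genotype)) {
    a <- genotype[[l]]
    ok <- ok & pmin(gm[, l], gp[, l]) == a[1] & pmax(gm[, l], gp[, l]) == a[2]
  }
  est <- mean(ok)
  list(estimate = est, se = sqrt(est * (1 - est) / n_draws),
       n_draws = n_draws)
}

#' Assemble simulated groups into one dataset with missing data
#'
#' Binds group datasets, then masks each locus call independently with
#' probability `missing_rate`, redrawing any individual's mask that would
#' exceed the per-individual missing cap so the emitted dataset always
#' validates.
#'
#' @param groups list of [genotype_dataset()] objects on identical loci.
#' @param missing_rate per-call missing probability (default 0.124, the
#'   scale of routine STR panels with one poorly scoring locus).
#' @param max_missing per-individual missing-locus cap (default 3).
#' @param seed integer seed.
#' @return a [genotype_dataset()].
#' @export
sample_dataset <- function(groups, missing_rate = 0.124, max_missing = 3L,
                           seed = 1L) {
  set.seed(seed)
  geno <- do.call(rbind, lapply(groups, `[[`, "geno"))
  rownames(geno) <- NULL
  loci <- groups[[1]]$loci
  L <- nrow(loci)
  if (missing_rate > 0) {
    for (i in seq_len(nrow(geno))) {
      repeat {
        mask <- stats::runif(L) < missing_rate
        if (sum(mask) <= max_missing) break
      }
      for (k in which(mask)) {
        geno[i, locus_cols(loci$name[k])] <- NA_integer_
      }
    }
  }
  genotype_dataset(geno, loci = loci, max_missing = max_missing)
}

#' Simulate a full parthenogen community
#'
#' Emulates the shape of a complete hybrid-parthenogen study panel: four
#' maternal bisexual populations and two paternal bisexual species (six
#' bisexual groups), and seven parthenogenetic species with mixed
#' ancestry — two sister pairs descending from single founders (one pair
#' diverged by backcrossing) and three independently founded lineages —
#' at ten loci with roughly 12% missing calls and clonal genotype
#' redundancy.
#'
#' @param n_partheno sample sizes of the seven parthenogen groups.
#' @param n_maternal sample sizes of the four maternal populations.
#' @param n_paternal sample sizes of the two paternal species.
#' @param loci a [locus_table()]; default [sim_loci()].
#' @param G,mu,conv clonal propagation parameters as in
#'   [simulate_scenario()].
#' @param missing_rate per-call missing probability (default 0.124).
#' @param seed integer seed.
#' @return list with `dataset`, `roles` (data.frame: parthenogen, maternal
#'   group, origin tag), `parental_freqs`, and `founders`.
#' @export
simulate_community <- function(n_partheno = c(44L, 29L, 27L, 17L, 19L, 14L, 15L),
                               n_maternal = c(42L, 30L, 25L, 20L),
                               n_paternal = c(35L, 40L),
                               loci = sim_loci(), G = 50L, mu = 0.005,
                               conv = 0.005, missing_rate = 0.124,
                               seed = 1L) {
  stopifnot(length(n_partheno) == 7L, length(n_maternal) == 4L,
            length(n_paternal) == 2L)
  sd <- function(k) (seed * 7919L + k) %% .Machine$integer.max
  groups <- list()
  mfreqs <- list()
  for (i in 1:4) {
    nm <- sprintf("maternal%d", i)
    mfreqs[[nm]] <- draw_parental_freqs(loci, offset = 0L, seed = sd(i))
    groups[[nm]] <- simulate_parental_population(mfreqs[[nm]], n_maternal[i],
                                                 loci, species = nm,
                                                 seed = sd(10 + i))
  }
  pfreqs <- list()
  for (i in 1:2) {
    nm <- sprintf("paternal%d", i)
    pfreqs[[nm]] <- draw_parental_freqs(loci, offset = 10L + 5L * (i - 1L),
                                        seed = sd(20 + i))
    groups[[nm]] <- simulate_parental_population(pfreqs[[nm]], n_paternal[i],
                                                 loci, species = nm,
                                                 seed = sd(30 + i))
  }
  # ancestry plan: (p1, p2) single origin + backcross divergence from
  # maternal1 x paternal1; (p6, p7) plain single origin from maternal4 x
  # paternal2; p3..p5 independent origins
  plan <- data.frame(
    parthenogen = sprintf("partheno%d", 1:7),
    maternal = c("maternal1", "maternal1", "maternal2", "maternal2",
                 "maternal3", "maternal4", "maternal4"),
    paternal = c("paternal1", "paternal1", "paternal2", "paternal1",
                 "paternal2", "paternal2", "paternal2"),
    stringsAsFactors = FALSE)
  founders <- list()
  f12 <- form_hybrid(groups[["maternal1"]], groups[["paternal1"]],
                     seed = sd(41))
  f67 <- form_hybrid(groups[["maternal4"]], groups[["paternal2"]],
                     seed = sd(42))
  origin <- character(7)
  for (s in 1:7) {
    sp <- plan$parthenogen[s]
    if (s == 1L) { f <- f12; origin[s] <- "founderA" }
    else if (s == 2L) {
      f <- backcross(f12, groups[[plan$paternal[s]]], 0.3,
                     seed = sd(43))$founder
      origin[s] <- "founderA+backcross"
    } else if (s == 6L) { f <- f67; origin[s] <- "founderB" }
    else if (s == 7L) { f <- f67; origin[s] <- "founderB" }
    else {
      f <- form_hybrid(groups[[plan$maternal[s]]], groups[[plan$paternal[s]]],
                       seed = sd(50 + s))
      origin[s] <- sprintf("founder%d", s)
    }
    founders[[sp]] <- f
    groups[[sp]] <- evolve_clonal_lineage(f, n = n_partheno[s], G = G,
                                          mu = mu, conv = conv, species = sp,
                                          seed = sd(60 + s))$dataset
  }
  plan$origin <- origin
  dataset <- sample_dataset(groups, missing_rate = missing_rate,
                            seed = sd(99))
  list(dataset = dataset, roles = plan,
       parental_freqs = list(maternal = mfreqs, paternal = pfreqs),
       founders = founders)
}

#' Simulate a full origin scenario
#'
#' Builds maternal and paternal bisexual populations, founds parthenogen
#' groups either from one common hybrid founder (`"single_origin"`, with
#' optional backcross divergence between the daughter species) or from
#' independent founders (`"independent_origin"`), evolves each clonal
#' group, and assembles the final dataset with missing data.
#'
#' @param type `"single_origin"` or `"independent_origin"`.
#' @param n_parthenogens number of parthenogen species (default 2).
#' @param n_per_group individuals per parthenogen group (recycled).
#' @param n_parental individuals per bisexual group.
#' @param loci a [locus_table()]; default [sim_loci()].
#' @param G generations of clonal propagation (default 50).
#' @param mu stepwise mutation rate (default 0.005/locus/generation).
#' @param conv conversion rate (default 0.005/locus/generation).
#' @param backcross_prob if > 0 (single origin only), the second and later
#'   parthenogen species are re-founded by a backcross replacing each
#'   paternal allele with this probability.
#' @param missing_rate per-call missing probability (default 0.124).
#' @param concentration Dirichlet concentration for parental frequencies.
#' @param seed integer seed; all internal seeds derive from it.
#' @return list with `dataset` (parentals + parthenogens),
#'   `parental_freqs` (list: maternal/paternal frequency specs), `founders`
#'   (per parthenogen), `truth` (origin map and per-group event logs).
#' @export
simulate_scenario <- function(type = c("single_origin", "independent_origin"),
                              n_parthenogens = 2L, n_per_group = 30L,
                              n_parental = 40L, loci = sim_loci(),
                              G = 50L, mu = 0.005, conv = 0.005,
                              backcross_prob = 0, missing_rate = 0.124,
                              concentration = 1, seed = 1L) {
  type <- match.arg(type)
  n_per_group <- rep_len(n_per_group, n_parthenogens)
  sd <- function(k) (seed * 1000L + k) %% .Machine$integer.max
  mfreq <- draw_parental_freqs(loci, offset = 0L, concentration = concentration,
                               seed = sd(1))
  pfreq <- draw_parental_freqs(loci, offset = 10L, concentration = concentration,
                               seed = sd(2))
  maternal <- simulate_parental_population(mfreq, n_parental, loci,
                                           species = "maternal", seed = sd(3))
  paternal <- simulate_parental_population(pfreq, n_parental, loci,
                                           species = "paternal", seed = sd(4))
  founders <- list()
  groups <- list(maternal = maternal, paternal = paternal)
  origin <- character(n_parthenogens)
  events <- list()
  base_founder <- form_hybrid(maternal, paternal, seed = sd(5))
  for (s in seq_len(n_parthenogens)) {
    sp <- sprintf("partheno%d", s)
    if (type == "single_origin") {
      f <- base_founder
      origin[s] <- "founder1"
      if (s > 1L && backcross_prob > 0) {
        bc <- backcross(f, paternal, backcross_prob, seed = sd(10 + s))
        f <- bc$founder
        origin[s] <- "founder1+backcross"
      }
    } else {
      f <- if (s == 1L) base_founder else
        form_hybrid(maternal, paternal, seed = sd(20 + s))
      origin[s] <- sprintf("founder%d", s)
    }
    founders[[sp]] <- f
    lin <- evolve_clonal_lineage(f, n = n_per_group[s], G = G, mu = mu,
                                 conv = conv, species = sp, seed = sd(30 + s))
    groups[[sp]] <- lin$dataset
    events[[sp]] <- lin$events
  }
  dataset <- sample_dataset(groups, missing_rate = missing_rate,
                            seed = sd(99))
  list(dataset = dataset,
       parental_freqs = list(maternal = mfreq, paternal = pfreq),
       founders = founders,
       truth = list(type = type, origin = origin, events = events,
                    G = G, mu = mu, conv = conv, seed = seed))
}
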