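# Shared fixture builders. Everything is constructed in code; allele sizes
# are chosen on simple ladders so repeat-unit arithmetic is easy to check
# by hand.

# A wide-format data.frame for n individuals at the given loci, from a
# list of rows: list(id, species, pop, calls = list(locus = c(a, b))).
toy_geno_df <- function(rows, loci) {
  df <- data.frame(
    id = vapply(rows, `[[`, "", "id"),
    species = vapply(rows, `[[`, "", "species"),
    population = vapply(rows, function(r)
      if (is.null(r$population)) r$species else r$population, ""),
    stringsAsFactors = FALSE)
  for (l in loci$name) {
    df[[paste0(l, ".1")]] <- vapply(rows, function(r) {
      a <- r$calls[[l]]
      if (is.null(a)) NA_integer_ else as.integer(a[1])
    }, integer(1))
    df[[paste0(l, ".2")]] <- vapply(rows, function(r) {
      a <- r$calls[[l]]
      if (is.null(a)) NA_integer_ else as.integer(a[2])
    }, integer(1))
  }
  df
}

toy_dataset <- function(rows, loci) genotype_dataset(toy_geno_df(rows, loci), loci)

# two tetranucleotide loci, zero offset
loci2 <- function() locus_table(c("LA", "LB"), motif_length = 4L)

# quick row constructor
ind <- function(id, species, ...) {
  list(id = id, species = species, calls = list(...))
}

# random complete dataset used for round-trip and invariance properties
random_dataset <- function(n = 12, seed = 42) {
  loci <- sim_loci(5)
  freqs <- draw_parental_freqs(loci, n_alleles = 4, seed = seed)
  simulate_parental_population(freqs, n, loci, species = "rand", seed = seed)
}

# independent Bruvo oracle: per-locus brute force over both pairings,
# written from the closed form, no package internals
oracle_bruvo <- function(pairA, pairB, motif) {
  ra <- pairA / motif; rb <- pairB / motif
  d <- function(x, y) 1 - 2^(-abs(x - y))
  per <- min((d(ra[1], rb[1]) + d(ra[2], rb[2])) / 2,
             (d(ra[1], rb[2]) + d(ra[2], rb[1])) / 2)
  per
}
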