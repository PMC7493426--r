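# Probability model for independent coincidence of multilocus genotypes
# in hybrid parthenogens.
#
# A hybrid clone's founding genotype is one paternal plus one maternal
# gamete. For a heterozygous locus with alleles i and j the formation
# probability is p_i*q_j + p_j*q_i (either allele may have come from
# either parent); loci multiply because gametes assort independently. A
# homozygous locus i/i can be scored two ways: "random_union" demands the
# allele from both parents (p_i*q_i), while the conservative "conversion"
# mode assumes the locus lost heterozygosity after hybridization and only
# one of the two founding alleles — equally likely either — survives,
# giving (p_i + q_i)/2. Coincidence across two or three independently
# founded lineages multiplies the per-lineage formation probabilities
# (squaring/cubing when the parental pools coincide).

#' Construct a multilocus genotype
#'
#' @param ... named arguments, one per locus, each a length-2 vector of
#'   allele sizes, e.g. `Du183 = c(189, 193)`; or a single named list.
#' @return a named list of sorted integer allele pairs, class
#'   `multilocus_genotype`.
#' @examples
#' multilocus_genotype(Du183 = c(189, 193), Du47 = c(278, 286))
#' @export
multilocus_genotype <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && is.null(names(args))) {
    args <- args[[1]]
  }
  if (is.null(names(args)) || any(!nzchar(names(args)))) {
    stop("every locus must be named")
  }
  g <- lapply(args, function(a) {
    if (length(a) != 2L || anyNA(a)) stop("each locus needs two present alleles")
    sort(as.integer(a))
  })
  structure(g, class = "multilocus_genotype")
}

#' Parse a genotype specification string
#'
#' Accepts the CLI syntax `"locus=a/b,locus=a/b"`, e.g.
#' `"Du183=189/193,Du47=278/286"`.
#'
#' @param spec specification string.
#' @return a [multilocus_genotype()].
#' @export
parse_genotype <- function(spec) {
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  alleles <- lapply(kv, function(p) as.integer(strsplit(p[2], "/")[[1]]))
  names(alleles) <- vapply(kv, `[[`, "", 1)
  multilocus_genotype(alleles)
}

freq_of <- function(tab, locus, allele) {
  if (!locus %in% names(tab$freqs)) {
    stop("locus absent from frequency table '", tab$group, "': ", locus)
  }
  f <- tab$freqs[[locus]][as.character(allele)]
  if (is.na(f)) 0 else as.numeric(f)
}

#' Hybrid formation probability of a multilocus genotype
#'
#' Per-locus factors: heterozygous i/j gives `p_i*q_j + p_j*q_i`;
#' homozygous i/i gives `(p_i + q_i)/2` under `hom_mode = "conversion"`
#' (heterozygosity loss, either founding allele retained with equal
#' probability — the conservative choice since `(p+q)/2 >= p*q` always) or
#' `p_i*q_i` under `"random_union"`. The genotype probability is the
#' product over loci. An allele absent from a parental table contributes a
#' zero factor and is flagged, not an error.
#'
#' @param genotype a [multilocus_genotype()].
#' @param paternal,maternal `freq_table` objects (see
#'   [allele_frequencies()]) holding `p` and `q`.
#' @param hom_mode `"conversion"` or `"random_union"`.
#' @return list with `prob`, `factors` (named per-locus), `zygosity`, and
#'   `zero_frequency` (data.frame of (table, locus, allele) with zero
#'   frequency).
#' @export
hybrid_formation_prob <- function(genotype, paternal, maternal,
                                  hom_mode = c("conversion", "random_union")) {
  hom_mode <- match.arg(hom_mode)
  factors <- numeric(0)
  zygosity <- character(0)
  zero <- list()
  for (l in names(genotype)) {
    a <- genotype[[l]]
    p1 <- freq_of(paternal, l, a[1]); p2 <- freq_of(paternal, l, a[2])
    q1 <- freq_of(maternal, l, a[1]); q2 <- freq_of(maternal, l, a[2])
    for (al in unique(a)) {
      if (freq_of(paternal, l, al) == 0) {
        zero[[length(zero) + 1L]] <- data.frame(
          table = paternal$group, locus = l, allele = al)
      }
      if (freq_of(maternal, l, al) == 0) {
        zero[[length(zero) + 1L]] <- data.frame(
          table = maternal$group, locus = l, allele = al)
      }
    }
    if (a[1] == a[2]) {
      zygosity[l] <- "hom"
      factors[l] <- if (hom_mode == "conversion") (p1 + q1) / 2 else p1 * q1
    } else {
      zygosity[l] <- "het"
      factors[l] <- p1 * q2 + p2 * q1
    }
  }
  list(prob = prod(factors), factors = factors, zygosity = zygosity,
       hom_mode = hom_mode,
       zero_frequency = if (length(zero)) do.call(rbind, zero) else
         data.frame(table = character(0), locus = character(0),
                    allele = integer(0)))
}

#' Brute-force formation probability by gamete-phase enumeration
#'
#' Independent oracle for the factorized formula on all-heterozygous
#' genotypes: sums, over all `2^n` assignments of which allele at each
#' locus came from the paternal gamete, the product of paternal and
#' maternal allele frequencies. For two loci this is the explicit 4-term
#' expansion `p_A1 p_B1 q_A2 q_B2 + p_A2 p_B1 q_A1 q_B2 +
#' p_A2 p_B2 q_A1 q_B1 + p_A1 p_B2 q_A2 q_B1`.
#'
#' @inheritParams hybrid_formation_prob
#' @return the probability (a single number).
#' @export
enumerate_formation_prob <- function(genotype, paternal, maternal) {
  n <- length(genotype)
  if (n > 20L) stop("enumeration limited to 20 loci")
  for (l in names(genotype)) {
    if (genotype[[l]][1] == genotype[[l]][2]) {
      stop("enumeration oracle handles heterozygous loci only (locus ", l, ")")
    }
  }
  total <- 0
  for (mask in 0:(2^n - 1)) {
    term <- 1
    for (k in seq_len(n)) {
      l <- names(genotype)[k]
      a <- genotype[[l]]
      pat <- if (bitwAnd(mask, bitwShiftL(1L, k - 1L)) > 0) a[1] else a[2]
      mat <- setdiff(a, pat)
      term <- term * freq_of(paternal, l, pat) * freq_of(maternal, l, mat)
    }
    total <- total + term
  }
  total
}

#' Coincidence probability across independently founded lineages
#'
#' Probability that the same multilocus genotype is formed independently
#' in each of 2 or 3 parthenogenetic lineages, given each lineage's
#' parental frequency pair: the product of per-lineage formation
#' probabilities. Supplying the same parental pair twice (or thrice)
#' reduces to squaring (cubing) the formation probability.
#'
#' @param genotype a [multilocus_genotype()].
#' @param parental_pairs list (length 2 or 3) of `list(paternal =, maternal =)`
#'   frequency-table pairs, one per putative independent origin.
#' @param hom_mode `"conversion"` or `"random_union"`.
#' @return list with `coincidence_prob`, `formation` (list of per-lineage
#'   [hybrid_formation_prob()] results), and `zero_frequency` (combined
#'   flags).
#' @export
coincidence_prob <- function(genotype, parental_pairs,
                             hom_mode = c("conversion", "random_union")) {
  hom_mode <- match.arg(hom_mode)
  if (!length(parental_pairs) %in% 2:3) {
    stop("parental_pairs must have length 2 or 3")
  }
  formation <- lapply(parental_pairs, function(pp) {
    hybrid_formation_prob(genotype, pp$paternal, pp$maternal, hom_mode)
  })
  list(
    coincidence_prob = prod(vapply(formation, `[[`, numeric(1), "prob")),
    formation = formation,
    zero_frequency = do.call(rbind, lapply(formation, `[[`, "zero_frequency"))
  )
}

#' Theoretical coincidence curves versus number of loci
#'
#' Idealized curves with every allele in every population at a common
#' frequency `freq` (the published illustration uses 1/2):
#'
#' * `"a"` two unisexual lineages, any zygosity modelled as heterozygous
#'   formation: `[(2 freq^2)^n]^2`.
#' * `"b"` a parthenogen and a bisexual population, all-heterozygous
#'   genotype: formation probability times the Hardy-Weinberg heterozygote
#'   product, `(2 freq^2)^n * (2 freq^2)^n`.
#' * `"c"` a parthenogen and a bisexual population, all-homozygous
#'   genotype: conversion-mode formation times the Hardy-Weinberg
#'   homozygote product, `freq^n * (freq^2)^n`.
#' * `"d"` two parthenogens via allelic conversion (homozygous only):
#'   `[freq^n]^2`.
#'
#' @param scenario `"a"`, `"b"`, `"c"` or `"d"`.
#' @param n_max maximum number of loci.
#' @param freq common allele frequency in (0, 1).
#' @return numeric vector of probabilities for `n = 1..n_max`.
#' @export
theoretical_curves <- function(scenario = c("a", "b", "c", "d"), n_max = 10L,
                               freq = 0.5) {
  scenario <- match.arg(scenario)
  stopifnot(freq > 0, freq < 1, n_max >= 1)
  n <- seq_len(n_max)
  het <- 2 * freq^2          # heterozygous formation factor p*q + q*p
  hom <- freq                # conversion-mode homozygous factor (p+q)/2
  switch(scenario,
    a = (het^n)^2,
    b = het^n * (2 * freq * freq)^n,
    c = hom^n * (freq^2)^n,
    d = (hom^n)^2
  )
}

#' Balanced-gamete probability for a triploid
#'
#' Probability that a triploid's meiosis sends every univalent to the same
#' pole, yielding a balanced (haploid or diploid) gamete: `0.5^(x-1)` for
#' haploid chromosome number `x`. With x = 19 this is about 3.81e-6, one
#' in 262,144 gametes.
#'
#' @param x haploid chromosome number (integer >= 1).
#' @return list with `prob` and exact integer `reciprocal` (`2^(x-1)`).
#' @export
triploid_balanced_gamete_prob <- function(x) {
  if (length(x) != 1L || is.na(x) || x != round(x) || x < 1) {
    stop("x must be a single integer >= 1")
  }
  list(prob = 0.5^(x - 1), reciprocal = 2^(x - 1))
}

#' Build a frequency table directly from allele frequencies
#'
#' Convenience constructor for model calculations when frequencies are
#' stated rather than estimated from data.
#'
#' @param freqs named list: locus -> named numeric vector (names = allele
#'   sizes) summing to 1.
#' @param group label.
#' @param n_scored scored gene copies per locus (default 100 each, only
#'   used by pooling).
#' @return a `freq_table`.
#' @export
freq_table <- function(freqs, group = "manual", n_scored = NULL) {
  for (l in names(freqs)) {
    if (abs(sum(freqs[[l]]) - 1) > 1e-9) {
      stop("frequencies at locus ", l, " do not sum to 1")
    }
  }
  if (is.null(n_scored)) {
    n_scored <- stats::setNames(rep(100L, length(freqs)), names(freqs))
  }
  structure(list(group = group, freqs = freqs, n_scored = n_scored),
            unscored = character(0), class = "freq_table")
}
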