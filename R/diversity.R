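# Per-group diversity and clonal genotype statistics.

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a standardized subsample of `g`
#' gene copies, by hypergeometric rarefaction: per locus
#' \deqn{AR = \sum_a \left[1 - \binom{n - n_a}{g} / \binom{n}{g}\right]}
#' where \eqn{n} is the number of scored gene copies and \eqn{n_a} the count
#' of allele \eqn{a}. Summing over alleles gives the expected allele count
#' among `g` randomly drawn copies, which makes richness comparable across
#' groups with unequal sample sizes.
#'
#' @param dataset a [genotype_dataset()].
#' @param group group label.
#' @param g rarefaction size in gene copies; default the minimum scored
#'   copies over loci in the group. Must be >= 2 and <= that minimum.
#' @param group_by `"species"` or `"population"`.
#' @return list with `per_locus` (named AR vector), `total` (sum across
#'   loci), `g`, and `excluded` (unscored loci).
#' @export
rarefied_allelic_richness <- function(dataset, group, g = NULL,
                                      group_by = "species") {
  tab <- allele_frequencies(dataset, group_by = group_by, groups = group)[[1]]
  if (length(tab$n_scored) == 0L) stop("group has no scored loci")
  gmax <- min(tab$n_scored)
  if (is.null(g)) g <- gmax
  if (g < 2) stop("rarefaction size g must be >= 2")
  if (g > gmax) stop(sprintf("g = %d exceeds minimum scored copies (%d)", g, gmax))
  per_locus <- vapply(names(tab$freqs), function(l) {
    n <- tab$n_scored[[l]]
    counts <- round(tab$freqs[[l]] * n)
    # 1 - C(n - n_a, g)/C(n, g), in log space for numerical safety
    sum(1 - exp(lchoose(n - counts, g) - lchoose(n, g)))
  }, numeric(1))
  list(per_locus = per_locus, total = sum(per_locus), g = as.integer(g),
       excluded = attr(tab, "unscored"))
}

#' Observed and expected heterozygosity
#'
#' OH is the fraction of scored calls that are heterozygous, averaged over
#' loci; EH is the unbiased expected heterozygosity
#' \eqn{\frac{n}{n-1}(1 - \sum_a p_a^2)} per locus (n = scored gene
#' copies), averaged over loci with n >= 2 copies from >= 2 individuals;
#' `hoz` is the overall proportion of homozygous scored locus-calls pooled
#' over loci and individuals. Heterozygote excess `OH - EH` above zero is
#' the signature of frozen F1 hybrid genotypes in clonal lineages.
#'
#' @inheritParams rarefied_allelic_richness
#' @return list with `OH`, `EH`, `het_excess`, `hoz`, per-locus vectors
#'   `OH_locus` / `EH_locus`, and `EH_excluded` (loci with too few scored
#'   copies for the unbiased estimator, flagged not zero-filled).
#' @export
heterozygosity <- function(dataset, group, group_by = "species") {
  ds <- subset_group(dataset, group, group_by)
  a1 <- allele_matrix(ds, 1L)
  a2 <- allele_matrix(ds, 2L)
  het <- a1 != a2
  scored <- !is.na(a1)
  oh_locus <- colSums(het, na.rm = TRUE) / colSums(scored)
  oh_locus[colSums(scored) == 0L] <- NA_real_
  tab <- allele_frequencies(ds, group_by = group_by, groups = group)[[1]]
  eh_locus <- stats::setNames(rep(NA_real_, ncol(a1)), colnames(a1))
  for (l in names(tab$freqs)) {
    n <- tab$n_scored[[l]]
    if (n < 4L) next  # < 2 scored diploid individuals: estimator undefined
    p <- tab$freqs[[l]]
    eh_locus[l] <- n / (n - 1) * (1 - sum(p^2))
  }
  eh_excluded <- names(which(is.na(eh_locus) & colSums(scored) > 0))
  hoz <- sum(!het, na.rm = TRUE) / sum(scored)
  OH <- mean(oh_locus, na.rm = TRUE)
  EH <- mean(eh_locus, na.rm = TRUE)
  list(OH = OH, EH = EH, het_excess = OH - EH, hoz = hoz,
       OH_locus = oh_locus, EH_locus = eh_locus, EH_excluded = eh_excluded)
}

#' Clonal genotype diversity summary for one group
#'
#' Counts distinct multilocus genotypes with the clonal-census rule that
#' every individual carrying a missing call is its own genotype class, and
#' summarizes the spread of the clone distribution: `DR` is the Bruvo
#' distance between the two most distant distinct genotypes, `MD` the Bruvo
#' distance between the two most common ones, `top_freqs` the frequencies
#' of the four most common genotypes among individuals. Ties on frequency
#' are broken by lexicographic genotype key so results are reproducible.
#'
#' @inheritParams rarefied_allelic_richness
#' @return list with `group`, `N`, `GT`, `DR`, `MD`, `top_freqs`, and
#'   `degenerate` (TRUE when fewer than 2 distinct genotypes exist, in
#'   which case `DR = MD = 0`).
#' @export
genotype_diversity_table <- function(dataset, group, group_by = "species") {
  ds <- subset_group(dataset, group, group_by)
  keys <- genotype_keys(ds, distinct_missing = TRUE)
  N <- nrow(ds$geno)
  counts <- table(keys)
  GT <- length(counts)
  ord <- order(-as.numeric(counts), names(counts))
  freqs <- as.numeric(counts)[ord] / N
  top_freqs <- freqs[seq_len(min(4L, length(freqs)))]
  if (GT < 2L) {
    return(list(group = group, N = N, GT = GT, DR = 0, MD = 0,
                top_freqs = top_freqs, degenerate = TRUE))
  }
  reps <- match(names(counts)[ord], keys)  # representative individual per class
  D <- bruvo_distance_matrix(ds)$matrix[reps, reps, drop = FALSE]
  DR <- max(D, na.rm = TRUE)
  MD <- D[1, 2]
  list(group = group, N = N, GT = GT, DR = DR, MD = MD,
       top_freqs = top_freqs, degenerate = FALSE)
}

#' Diversity summary across groups
#'
#' Convenience wrapper producing one row per group with the clone-census
#' columns (N, GT, DR, MD, 1st..4th most common genotype frequency) and the
#' diversity panel (rarefied AR, OH - EH, HoZ). The rarefaction size
#' defaults to the smallest minimum scored copy count across the groups so
#' that AR is comparable among them.
#'
#' @param dataset a [genotype_dataset()].
#' @param groups group labels; default all species.
#' @param g rarefaction size in gene copies shared by all groups.
#' @param group_by `"species"` or `"population"`.
#' @return a data.frame, one row per group.
#' @export
diversity_summary <- function(dataset, groups = NULL, g = NULL,
                              group_by = "species") {
  if (is.null(groups)) groups <- unique(dataset$geno[[group_by]])
  if (is.null(g)) {
    g <- min(vapply(groups, function(gr) {
      tab <- allele_frequencies(dataset, group_by, gr)[[1]]
      min(tab$n_scored)
    }, numeric(1)))
  }
  rows <- lapply(groups, function(gr) {
    gt <- genotype_diversity_table(dataset, gr, group_by)
    ar <- rarefied_allelic_richness(dataset, gr, g = g, group_by = group_by)
    h <- heterozygosity(dataset, gr, group_by)
    tf <- c(gt$top_freqs, rep(NA_real_, 4L))[1:4]
    data.frame(group = gr, N = gt$N, GT = gt$GT, DR = gt$DR, MD = gt$MD,
               f1 = tf[1], f2 = tf[2], f3 = tf[3], f4 = tf[4],
               AR = ar$total, OH = h$OH, EH = h$EH,
               het_excess = h$het_excess, hoz = h$hoz,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "g") <- g
  out
}
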