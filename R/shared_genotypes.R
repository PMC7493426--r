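# Shared alleles and shared single-/multi-locus genotypes between groups.

# locus-call string keys for one group's individuals, NA when missing
call_keys <- function(dataset) {
  a1 <- allele_matrix(dataset, 1L)
  a2 <- allele_matrix(dataset, 2L)
  key <- matrix(paste0(a1, "/", a2), nrow = nrow(a1),
                dimnames = list(dataset$geno$id, colnames(a1)))
  key[is.na(a1)] <- NA
  key
}

#' Proportion of shared alleles between two individuals
#'
#' Per commonly scored locus the shared proportion is the size of the
#' multiset intersection of the two allele pairs divided by 2 (so one
#' allele in common scores 0.5); the individual-pair value is the mean over
#' commonly scored loci.
#'
#' @param dataset a [genotype_dataset()].
#' @param idA,idB individual ids.
#' @return proportion in `[0, 1]`, `NA` if no commonly scored locus.
#' @export
prop_shared_alleles <- function(dataset, idA, idB) {
  iA <- match(idA, dataset$geno$id)
  iB <- match(idB, dataset$geno$id)
  if (anyNA(c(iA, iB))) stop("unknown individual id")
  a1 <- allele_matrix(dataset, 1L)
  a2 <- allele_matrix(dataset, 2L)
  vals <- numeric(0)
  for (l in colnames(a1)) {
    pa <- c(a1[iA, l], a2[iA, l])
    pb <- c(a1[iB, l], a2[iB, l])
    if (anyNA(pa) || anyNA(pb)) next
    # multiset intersection size of two unordered pairs
    shared <- 0L
    for (x in pa) {
      hit <- match(x, pb)
      if (!is.na(hit)) { shared <- shared + 1L; pb <- pb[-hit] }
    }
    vals <- c(vals, shared / 2)
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Group-mean proportion of shared alleles
#'
#' Mean of [prop_shared_alleles()] over all cross-group individual pairs;
#' pairs with no commonly scored locus are excluded from the mean (not
#' zero-filled).
#'
#' @param dataset a [genotype_dataset()].
#' @param groupA,groupB group labels.
#' @param group_by `"species"` or `"population"`.
#' @return mean proportion in `[0, 1]`.
#' @export
group_shared_alleles <- function(dataset, groupA, groupB,
                                 group_by = "species") {
  idsA <- dataset$geno$id[dataset$geno[[group_by]] == groupA]
  idsB <- dataset$geno$id[dataset$geno[[group_by]] == groupB]
  if (length(idsA) == 0L || length(idsB) == 0L) stop("empty group")
  vals <- outer(idsA, idsB, Vectorize(function(a, b)
    prop_shared_alleles(dataset, a, b)))
  if (all(is.na(vals))) stop("no valid cross-group pairs")
  mean(vals, na.rm = TRUE)
}

#' Shared k-locus diploid genotype proportion between groups
#'
#' Treats each k-subset of loci as one synthetic haploid marker whose
#' "allele" is an individual's complete unordered diploid genotype on that
#' subset (individuals missing any subset locus are skipped for that
#' subset). For each cross-group individual pair and subset, the pair
#' shares the marker (1) or not (0); the returned value averages over
#' subsets and pairs. Requiring joint identity across more loci is
#' stricter, so the value is non-increasing in `k`.
#'
#' @param dataset a [genotype_dataset()].
#' @param groupA,groupB group labels.
#' @param k number of loci per subset (1 or 2 in routine use).
#' @param group_by `"species"` or `"population"`.
#' @return proportion in `[0, 1]`.
#' @export
shared_klocus_genotype_proportion <- function(dataset, groupA, groupB, k = 1L,
                                              group_by = "species") {
  L <- nrow(dataset$loci)
  if (k > L) stop("k exceeds the number of loci")
  keyA <- call_keys(subset_group(dataset, groupA, group_by))
  keyB <- call_keys(subset_group(dataset, groupB, group_by))
  subsets <- utils::combn(L, k, simplify = FALSE)
  vals <- numeric(0)
  for (s in subsets) {
    gA <- apply(keyA[, s, drop = FALSE], 1, function(r)
      if (anyNA(r)) NA_character_ else paste(r, collapse = "|"))
    gB <- apply(keyB[, s, drop = FALSE], 1, function(r)
      if (anyNA(r)) NA_character_ else paste(r, collapse = "|"))
    gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
    if (length(gA) == 0L || length(gB) == 0L) next  # flagged: no scored pairs
    vals <- c(vals, mean(outer(gA, gB, `==`)))
  }
  if (length(vals) == 0L) stop("no k-subset with scored pairs in both groups")
  mean(vals)
}

#' Maximum number of shared loci between two groups
#'
#' For every cross-group individual pair, counts loci at which the two
#' individuals carry the identical complete diploid genotype, and reports
#' per-individual and per-genotype-node maxima — the numbers annotated
#' next to MSN nodes.
#'
#' @param dataset a [genotype_dataset()].
#' @param groupA,groupB group labels.
#' @param group_by `"species"` or `"population"`.
#' @return list with `max` (overall maximum), `pair_matrix` (A x B counts),
#'   and `per_individual` (named vector: each individual's maximum count
#'   with any member of the other group).
#' @export
max_shared_loci <- function(dataset, groupA, groupB, group_by = "species") {
  keyA <- call_keys(subset_group(dataset, groupA, group_by))
  keyB <- call_keys(subset_group(dataset, groupB, group_by))
  M <- matrix(0L, nrow(keyA), nrow(keyB),
              dimnames = list(rownames(keyA), rownames(keyB)))
  for (i in seq_len(nrow(keyA))) {
    for (j in seq_len(nrow(keyB))) {
      M[i, j] <- sum(!is.na(keyA[i, ]) & !is.na(keyB[j, ]) &
                       keyA[i, ] == keyB[j, ])
    }
  }
  list(max = max(M),
       pair_matrix = M,
       per_individual = c(apply(M, 1, max), apply(M, 2, max)))
}

#' Discover multilocus genotypes shared between groups
#'
#' Enumerates locus subsets (sizes 1..`max_loci`) and, on each subset,
#' complete diploid genotypes carried in at least two of the requested
#' groups at carrier frequency >= `min_freq` in each. Carrier frequency is
#' carriers / individuals scored at all subset loci in that group
#' (individuals missing a subset locus leave the denominator). Only
#' maximal hits are kept: a report is dropped when a superset of its loci
#' carries an extension of its genotype in the same (or a larger) set of
#' groups. Results are sorted by number of groups, then number of loci,
#' then combined frequency, all decreasing.
#'
#' @param dataset a [genotype_dataset()].
#' @param groups group labels to compare (>= 2); default all species.
#' @param min_freq minimum per-group carrier frequency (default 0.05).
#' @param max_loci deepest subset size explored (default 6).
#' @param group_by `"species"` or `"population"`.
#' @return a data.frame with one row per shared genotype: `loci`
#'   (comma-separated), `n_loci`, `genotype` (locus=a/b pairs), `zygosity`
#'   (het/hom flags per locus), `groups`, `n_groups`, `freqs`
#'   (comma-separated per-group carrier frequencies, same order as
#'   `groups`), `combined_freq` (their sum).
#' @export
find_shared_multilocus_genotypes <- function(dataset, groups = NULL,
                                             min_freq = 0.05, max_loci = 6L,
                                             group_by = "species") {
  if (is.null(groups)) groups <- unique(dataset$geno[[group_by]])
  if (length(groups) < 2L) stop("need at least two groups")
  L <- nrow(dataset$loci)
  max_loci <- min(max_loci, L)
  keys <- lapply(groups, function(g) call_keys(subset_group(dataset, g, group_by)))
  names(keys) <- groups
  hits <- list()
  for (k in seq_len(max_loci)) {
    for (s in utils::combn(L, k, simplify = FALSE)) {
      per_group <- lapply(keys, function(km) {
        gk <- apply(km[, s, drop = FALSE], 1, function(r)
          if (anyNA(r)) NA_character_ else paste(r, collapse = "|"))
        gk <- gk[!is.na(gk)]
        if (length(gk) == 0L) return(NULL)
        table(gk) / length(gk)
      })
      shared <- Reduce(union, lapply(per_group, names))
      for (gt in shared) {
        f <- vapply(per_group, function(tb)
          if (is.null(tb) || is.na(tb[gt])) 0 else as.numeric(tb[gt]),
          numeric(1))
        carriers <- f >= min_freq & f > 0
        if (sum(carriers) >= 2L) {
          hits[[length(hits) + 1L]] <- list(
            loci = s, genotype = gt, groups = groups[carriers],
            freqs = f[carriers])
        }
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(loci = character(0), n_loci = integer(0),
                      genotype = character(0), zygosity = character(0),
                      groups = character(0), n_groups = integer(0),
                      freqs = character(0), combined_freq = numeric(0)))
  }
  # maximality: drop a hit if another hit's locus set strictly contains it,
  # restricts to the same genotype on the shared loci, and covers its groups
  keep <- rep(TRUE, length(hits))
  for (i in seq_along(hits)) {
    for (j in seq_along(hits)) {
      if (i == j || !keep[i]) next
      hi <- hits[[i]]; hj <- hits[[j]]
      if (length(hj$loci) > length(hi$loci) && all(hi$loci %in% hj$loci) &&
          all(hi$groups %in% hj$groups)) {
        pos <- match(hi$loci, hj$loci)
        proj <- paste(strsplit(hj$genotype, "|", fixed = TRUE)[[1]][pos],
                      collapse = "|")
        if (proj == hi$genotype) keep[i] <- FALSE
      }
    }
  }
  hits <- hits[keep]
  lnames <- dataset$loci$name
  rows <- lapply(hits, function(h) {
    calls <- strsplit(h$genotype, "|", fixed = TRUE)[[1]]
    ab <- strsplit(calls, "/", fixed = TRUE)
    zyg <- vapply(ab, function(p) if (p[1] == p[2]) "hom" else "het", "")
    data.frame(
      loci = paste(lnames[h$loci], collapse = ","),
      n_loci = length(h$loci),
      genotype = paste(paste0(lnames[h$loci], "=", calls), collapse = ";"),
      zygosity = paste(zyg, collapse = ","),
      groups = paste(h$groups, collapse = ","),
      n_groups = length(h$groups),
      freqs = paste(signif(h$freqs, 6), collapse = ","),
      combined_freq = sum(h$freqs),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_groups, -out$n_loci, -out$combined_freq,
                   out$genotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}
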