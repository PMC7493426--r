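# Data model and I/O for diploid microsatellite genotype tables.
#
# A genotype_dataset holds an ordered locus table (name, motif_length,
# reference_offset) and a wide data.frame of individuals: id, species,
# population, then two integer columns per locus named "<locus>.1" and
# "<locus>.2" (allele sizes in bp). A missing call sets both columns NA;
# half-calls are rejected. Allele pairs are unordered and stored
# canonically with the smaller size first.

MISSING_CODES <- c("0", "", "NA", "-9", "na", "?")

#' Define microsatellite loci
#'
#' Builds the locus metadata table used throughout the package. The repeat
#' motif length (bp per repeat unit) is what converts allele sizes in bp to
#' repeat counts for Bruvo distances; the optional reference offset is the
#' non-repeat flank length subtracted before division.
#'
#' @param name character vector of unique locus names.
#' @param motif_length positive integer vector (recycled), bp per repeat unit.
#' @param reference_offset integer vector (recycled), bp of non-repeat flank.
#' @return a data.frame with columns `name`, `motif_length`,
#'   `reference_offset`.
#' @examples
#' locus_table(c("Du183", "Du47"), motif_length = 4)
#' @export
locus_table <- function(name, motif_length = 2L, reference_offset = 0L) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("locus names must be unique")
  motif_length <- as.integer(rep_len(motif_length, length(name)))
  if (any(motif_length < 1L)) stop("motif_length must be >= 1")
  data.frame(
    name = name,
    motif_length = motif_length,
    reference_offset = as.integer(rep_len(reference_offset, length(name))),
    stringsAsFactors = FALSE
  )
}

locus_cols <- function(locus) paste0(locus, c(".1", ".2"))

#' Construct and validate a genotype dataset
#'
#' @param geno data.frame with columns `id`, `species`, `population` and two
#'   integer allele-size columns `<locus>.1`, `<locus>.2` per locus.
#' @param loci locus metadata from [locus_table()]. If `NULL`, loci are taken
#'   from the column names and motif lengths are inferred as the GCD of
#'   allele-size differences per locus (flagged in `attr(,"motif_inferred")`).
#' @param max_missing maximum number of missing loci allowed per individual
#'   (default 3, the scoring rule the data model enforces).
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(geno, loci = NULL, max_missing = 3L) {
  stopifnot(is.data.frame(geno))
  need <- c("id", "species", "population")
  if (!all(need %in% names(geno))) {
    stop("geno must have columns id, species, population")
  }
  allele_cols <- setdiff(names(geno), need)
  lnames <- unique(sub("\\.[12]$", "", allele_cols))
  if (!setequal(allele_cols, unlist(lapply(lnames, locus_cols)))) {
    stop("allele columns must come in pairs '<locus>.1', '<locus>.2'")
  }
  motif_inferred <- FALSE
  if (is.null(loci)) {
    loci <- locus_table(lnames, motif_length = 2L)
    loci$motif_length <- vapply(lnames, function(l) {
      infer_motif(c(geno[[locus_cols(l)[1]]], geno[[locus_cols(l)[2]]]))
    }, integer(1))
    motif_inferred <- TRUE
  }
  if (!all(lnames %in% loci$name)) {
    stop("unknown locus column(s): ",
         paste(setdiff(lnames, loci$name), collapse = ", "))
  }
  loci <- loci[match(lnames, loci$name), , drop = FALSE]
  rownames(loci) <- NULL
  if (nrow(loci) == 0L || nrow(geno) == 0L) {
    stop("dataset must have at least one locus and one individual")
  }
  geno$id <- as.character(geno$id)
  geno$species <- as.character(geno$species)
  geno$population <- as.character(geno$population)
  n_missing <- integer(nrow(geno))
  for (l in loci$name) {
    cls <- locus_cols(l)
    a1 <- as.integer(geno[[cls[1]]])
    a2 <- as.integer(geno[[cls[2]]])
    half <- xor(is.na(a1), is.na(a2))
    if (any(half)) {
      stop(sprintf("half-call at locus %s for individual(s): %s",
                   l, paste(geno$id[half], collapse = ", ")))
    }
    swap <- !is.na(a1) & a2 < a1
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
    geno[[cls[1]]] <- a1
    geno[[cls[2]]] <- a2
    n_missing <- n_missing + is.na(a1)
  }
  if (any(n_missing > max_missing)) {
    bad <- geno$id[n_missing > max_missing]
    stop(sprintf("individual(s) with more than %d missing loci: %s",
                 max_missing, paste(bad, collapse = ", ")))
  }
  structure(
    list(loci = loci, geno = geno[, c(need, unlist(lapply(loci$name, locus_cols)))]),
    max_missing = as.integer(max_missing),
    motif_inferred = motif_inferred,
    class = "genotype_dataset"
  )
}

# GCD-based motif inference from observed allele sizes at one locus.
infer_motif <- function(sizes) {
  sizes <- sort(unique(sizes[!is.na(sizes)]))
  if (length(sizes) < 2L) return(2L)
  d <- diff(sizes)
  g <- d[1]
  for (x in d[-1]) g <- gcd2(g, x)
  max(1L, as.integer(g))
}

gcd2 <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals, %d loci, %.2f%% missing\n",
              nrow(x$geno), nrow(x$loci), 100 * missing_rate(x)))
  cat("groups (species):",
      paste(sprintf("%s (%d)", names(table(x$geno$species)),
                    table(x$geno$species)), collapse = ", "), "\n")
  invisible(x)
}

#' Overall proportion of missing locus calls
#' @param dataset a [genotype_dataset()].
#' @return proportion of (individual, locus) calls that are missing.
#' @export
missing_rate <- function(dataset) {
  m <- allele_matrix(dataset, 1L)
  mean(is.na(m))
}

# n_individuals x n_loci matrix of allele `which` (1 or 2).
allele_matrix <- function(dataset, which) {
  cols <- paste0(dataset$loci$name, ".", which)
  m <- as.matrix(dataset$geno[, cols, drop = FALSE])
  colnames(m) <- dataset$loci$name
  m
}

#' Subset a dataset to one group
#' @param dataset a [genotype_dataset()].
#' @param group group label.
#' @param group_by `"species"` or `"population"`.
#' @return a `genotype_dataset` with only the matching individuals.
#' @export
subset_group <- function(dataset, group, group_by = "species") {
  group_by <- match.arg(group_by, c("species", "population"))
  keep <- dataset$geno[[group_by]] %in% group
  if (!any(keep)) stop("no individuals in group: ", paste(group, collapse = ","))
  out <- dataset
  out$geno <- dataset$geno[keep, , drop = FALSE]
  rownames(out$geno) <- NULL
  out
}

#' Read a genotype table
#'
#' Two dialects are supported, both CSV:
#'
#' * `"wide"`: header `id,species,population,<locus>.1,<locus>.2,...`; one
#'   row per individual.
#' * `"genalex"`: the GenAlEx export layout — row 1 holds
#'   `n_loci,n_individuals,n_pops,...`, row 2 a title, row 3 the header
#'   `id,pop,<locus>,,<locus>,,...` (each locus spanning two columns); the
#'   `pop` label fills both `species` and `population`.
#'
#' Missing-call encodings `0`, empty, `NA` and `-9` are normalized to
#' missing; allele pairs are stored with the smaller size first.
#'
#' @param path file path.
#' @param format `"wide"` or `"genalex"`.
#' @param loci optional [locus_table()]; inferred from columns if omitted.
#' @param max_missing per-individual missing-locus cap (default 3).
#' @return a [genotype_dataset()].
#' @export
read_genotype_table <- function(path, format = c("wide", "genalex"),
                                loci = NULL, max_missing = 3L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "wide") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  } else {
    raw <- utils::read.csv(path, header = FALSE, skip = 2,
                           stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
    hdr <- as.character(unlist(raw[1, ]))
    body <- raw[-1, , drop = FALSE]
    lnames <- hdr[seq(3, length(hdr), by = 2)]
    lnames <- lnames[nzchar(lnames)]
    df <- data.frame(id = body[[1]], species = body[[2]],
                     population = body[[2]], stringsAsFactors = FALSE)
    for (k in seq_along(lnames)) {
      df[[paste0(lnames[k], ".1")]] <- body[[2 * k + 1]]
      df[[paste0(lnames[k], ".2")]] <- body[[2 * k + 2]]
    }
  }
  allele_cols <- setdiff(names(df), c("id", "species", "population"))
  for (cl in allele_cols) {
    v <- trimws(df[[cl]])
    v[v %in% MISSING_CODES] <- NA
    num <- suppressWarnings(as.integer(v))
    bad <- !is.na(v) & is.na(num)
    if (any(bad)) {
      stop(sprintf("malformed allele value '%s' at column %s, row %d",
                   v[which(bad)[1]], cl, which(bad)[1]))
    }
    df[[cl]] <- num
  }
  genotype_dataset(df, loci = loci, max_missing = max_missing)
}

#' Write a genotype table (wide CSV dialect)
#' @param dataset a [genotype_dataset()].
#' @param path output file; missing calls written as `0`.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(dataset, path) {
  df <- dataset$geno
  for (cl in setdiff(names(df), c("id", "species", "population"))) {
    v <- df[[cl]]
    v[is.na(v)] <- 0L
    df[[cl]] <- v
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write locus metadata (TOML-style key-value file)
#'
#' The file holds one `[LocusName]` section per locus with integer keys
#' `motif_length` and (optionally) `reference_offset`.
#'
#' @param path file path.
#' @return [read_locus_meta()]: a [locus_table()] data.frame.
#' @export
read_locus_meta <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cur <- NULL
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      cur <- sub("^\\[(.+)\\]$", "\\1", ln)
      out[[cur]] <- list(motif_length = 2L, reference_offset = 0L)
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(cur)) stop("key-value line before any [locus] section")
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[cur]][[trimws(kv[1])]] <- as.integer(trimws(kv[2]))
    }
  }
  locus_table(names(out),
              motif_length = vapply(out, `[[`, integer(1), "motif_length"),
              reference_offset = vapply(out, `[[`, integer(1), "reference_offset"))
}

#' @rdname read_locus_meta
#' @param loci a [locus_table()] data.frame.
#' @export
write_locus_meta <- function(loci, path) {
  lines <- unlist(lapply(seq_len(nrow(loci)), function(i) {
    c(sprintf("[%s]", loci$name[i]),
      sprintf("motif_length = %d", loci$motif_length[i]),
      sprintf("reference_offset = %d", loci$reference_offset[i]), "")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Per-group allele frequencies
#'
#' Frequencies are allele counts over scored gene copies at each locus;
#' missing pairs are excluded from numerator and denominator. Loci with zero
#' scored copies in a group are omitted from the table and listed in
#' `attr(, "unscored")`.
#'
#' @param dataset a [genotype_dataset()].
#' @param group_by `"species"` or `"population"`.
#' @param groups labels to tabulate; default all groups present.
#' @return a named list of `freq_table` objects, each a list with `group`,
#'   `freqs` (locus -> named numeric vector of relative frequencies) and
#'   `n_scored` (locus -> scored gene copies).
#' @export
allele_frequencies <- function(dataset, group_by = "species", groups = NULL) {
  group_by <- match.arg(group_by, c("species", "population"))
  if (is.null(groups)) groups <- unique(dataset$geno[[group_by]])
  a1 <- allele_matrix(dataset, 1L)
  a2 <- allele_matrix(dataset, 2L)
  out <- lapply(groups, function(g) {
    sel <- dataset$geno[[group_by]] == g
    if (!any(sel)) stop("no individuals in group: ", g)
    freqs <- list()
    n_scored <- integer(0)
    unscored <- character(0)
    for (l in dataset$loci$name) {
      alleles <- c(a1[sel, l], a2[sel, l])
      alleles <- alleles[!is.na(alleles)]
      if (length(alleles) == 0L) {
        unscored <- c(unscored, l)
        next
      }
      tab <- table(alleles)
      freqs[[l]] <- stats::setNames(as.numeric(tab) / length(alleles),
                                    names(tab))
      n_scored[l] <- length(alleles)
    }
    structure(list(group = g, freqs = freqs, n_scored = n_scored),
              unscored = unscored, class = "freq_table")
  })
  stats::setNames(out, groups)
}

#' Pool allele-frequency tables across groups
#'
#' `"by_sample"` reconstitutes allele counts from frequencies and scored
#' copy numbers, sums them and renormalizes (equivalent to computing
#' frequencies on the concatenated raw data); `"equal"` averages the
#' frequency vectors with equal weight per group. Only loci scored in every
#' input table are kept; dropped loci are listed in `attr(, "dropped_loci")`.
#'
#' @param tables list of `freq_table` objects.
#' @param weights `"by_sample"` or `"equal"`.
#' @param group label for the pooled table.
#' @return a `freq_table`.
#' @export
pool_groups <- function(tables, weights = c("by_sample", "equal"),
                        group = "pooled") {
  weights <- match.arg(weights)
  if (length(tables) == 0L) stop("no tables to pool")
  loci_sets <- lapply(tables, function(t) names(t$freqs))
  common <- Reduce(intersect, loci_sets)
  dropped <- setdiff(unique(unlist(loci_sets)), common)
  if (length(common) == 0L) stop("no locus scored in all pooled groups")
  freqs <- list()
  n_scored <- integer(0)
  for (l in common) {
    alleles <- sort(unique(unlist(lapply(tables, function(t) names(t$freqs[[l]])))))
    acc <- stats::setNames(numeric(length(alleles)), alleles)
    ntot <- 0L
    for (t in tables) {
      f <- t$freqs[[l]]
      if (weights == "by_sample") {
        acc[names(f)] <- acc[names(f)] + f * t$n_scored[[l]]
        ntot <- ntot + t$n_scored[[l]]
      } else {
        acc[names(f)] <- acc[names(f)] + f / length(tables)
      }
    }
    if (weights == "by_sample") acc <- acc / ntot else ntot <- sum(
      vapply(tables, function(t) t$n_scored[[l]], numeric(1)))
    freqs[[l]] <- acc[acc > 0]
    n_scored[l] <- as.integer(ntot)
  }
  structure(list(group = group, freqs = freqs, n_scored = n_scored),
            unscored = character(0), dropped_loci = dropped,
            class = "freq_table")
}

#' Convert allele sizes to repeat counts
#'
#' `repeats = round((size_bp - reference_offset) / motif_length)`. Sizes
#' landing a quarter repeat unit or more off the ladder are flagged
#' off-ladder in `attr(, "off_ladder")` but still rounded.
#'
#' @param size_bp integer vector of allele sizes; no missing values.
#' @param locus one row of a [locus_table()] (or any list with
#'   `motif_length` and `reference_offset`).
#' @return integer repeat counts with logical attribute `off_ladder`.
#' @export
to_repeat_units <- function(size_bp, locus) {
  if (anyNA(size_bp)) stop("missing allele size in to_repeat_units")
  raw <- (as.numeric(size_bp) - locus$reference_offset) / locus$motif_length
  cnt <- round(raw)
  structure(as.integer(cnt), off_ladder = abs(raw - cnt) >= 0.25 - 1e-9)
}

#' Export a frequency table as long-format TSV
#' @param table a `freq_table`.
#' @param path output path; columns group, locus, allele_bp, frequency,
#'   n_copies.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(table, path) {
  rows <- do.call(rbind, lapply(names(table$freqs), function(l) {
    f <- table$freqs[[l]]
    data.frame(group = table$group, locus = l,
               allele_bp = as.integer(names(f)), frequency = as.numeric(f),
               n_copies = table$n_scored[[l]], stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- internal genotype-key helpers shared by several modules ------------

# Canonical string key of an individual's multilocus genotype; missing
# calls print as "?". Each individual with any missing locus gets a unique
# key when distinct_missing = TRUE (the clonal-diversity counting rule).
genotype_keys <- function(dataset, distinct_missing = FALSE) {
  a1 <- allele_matrix(dataset, 1L)
  a2 <- allele_matrix(dataset, 2L)
  per_locus <- matrix(paste0(a1, "/", a2), nrow = nrow(a1))
  per_locus[is.na(a1)] <- "?"
  keys <- apply(per_locus, 1, paste, collapse = ";")
  if (distinct_missing) {
    has_na <- rowSums(is.na(a1)) > 0
    keys[has_na] <- paste0(keys[has_na], "#", dataset$geno$id[has_na])
  }
  keys
}

# Number of heterozygous scored loci per individual.
n_heterozygous <- function(dataset) {
  a1 <- allele_matrix(dataset, 1L)
  a2 <- allele_matrix(dataset, 2L)
  rowSums(a1 != a2, na.rm = TRUE)
}

#' Drop near-homozygous individuals
#'
#' Removes every individual with fewer than `min_het` heterozygous scored
#' loci — the filter used to build heterozygote-only distance matrices that
#' suppress the signal of allelic conversion.
#'
#' @param dataset a [genotype_dataset()].
#' @param min_het minimum heterozygous loci retained individuals must have
#'   (default 2, i.e. individuals with none or one are dropped).
#' @return a filtered `genotype_dataset`.
#' @export
filter_heterozygotes <- function(dataset, min_het = 2L) {
  keep <- n_heterozygous(dataset) >= min_het
  if (!any(keep)) stop("no individuals pass the heterozygosity filter")
  out <- dataset
  out$geno <- dataset$geno[keep, , drop = FALSE]
  rownames(out$geno) <- NULL
  out
}
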