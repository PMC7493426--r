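# Pipeline orchestration: run the full analysis sequence on a genotype
# table and write a reproducible report bundle.

#' Read a minimal TOML-style config file
#'
#' Supports `[section]` headers, `key = value` lines with strings
#' (quoted), numbers, booleans and flat arrays (`["a", "b"]`), and `#`
#' comments. Sections become nested lists.
#'
#' @param path file path.
#' @return a nested named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  parse_val <- function(v) {
    v <- trimws(v)
    if (grepl("^\\[.*\\]$", v)) {
      inner <- trimws(strsplit(sub("^\\[(.*)\\]$", "\\1", v), ",")[[1]])
      return(unlist(lapply(inner, parse_val)))
    }
    if (grepl('^".*"$', v)) return(sub('^"(.*)"$', "\\1", v))
    if (v %in% c("true", "false")) return(v == "true")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  }
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- trimws(substr(ln, 1, eq - 1))
      val <- parse_val(substr(ln, eq + 1, nchar(ln)))
      if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
    }
  }
  out
}

#' Build a pipeline configuration
#'
#' @param parthenogens character vector of parthenogen species labels.
#' @param maternal named character vector mapping each parthenogen to its
#'   maternal bisexual species.
#' @param paternal character vector of paternal bisexual species (pooled
#'   by sample size for the coincidence model).
#' @param analyses subset of `c("diversity", "shared", "networks",
#'   "coincidence")`.
#' @param hom_mode `"conversion"` or `"random_union"`.
#' @param g rarefaction size in gene copies (`NULL` = smallest group
#'   minimum).
#' @param min_freq,max_loci shared-genotype discovery thresholds.
#' @param seed integer seed recorded in the manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(parthenogens, maternal, paternal,
                            analyses = c("diversity", "shared", "networks",
                                         "coincidence"),
                            hom_mode = "conversion", g = NULL,
                            min_freq = 0.05, max_loci = 6L, seed = 1L) {
  if (!all(parthenogens %in% names(maternal))) {
    stop("every parthenogen needs a maternal group mapping")
  }
  if (length(paternal) < 1L) stop("need at least one paternal group")
  structure(list(parthenogens = parthenogens, maternal = maternal,
                 paternal = paternal, analyses = analyses,
                 hom_mode = hom_mode, g = g, min_freq = min_freq,
                 max_loci = max_loci, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes, per the configured toggles: the per-group diversity table;
#' the cross-group shared-allele matrix and 1-/2-locus shared genotype
#' proportions; shared multilocus genotype discovery with coincidence
#' probabilities for every discovered genotype (paternal groups pooled by
#' sample, each species' own maternal group); the Bruvo distance matrix,
#' minimum spanning network and NJ tree over parthenogen individuals. All
#' outputs land in `out_dir` together with a manifest (config hash, seed,
#' package version) and a stage log.
#'
#' @param dataset a [genotype_dataset()] containing all referenced groups.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return list of in-memory stage results, invisibly; files in `out_dir`.
#' @export
run_pipeline <- function(dataset, config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  present <- unique(dataset$geno$species)
  referenced <- unique(c(config$parthenogens, config$maternal, config$paternal))
  if (!all(referenced %in% present)) {
    stop("groups missing from dataset: ",
         paste(setdiff(referenced, present), collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  results <- list()
  note("individuals=%d loci=%d missing=%.4f", nrow(dataset$geno),
       nrow(dataset$loci), missing_rate(dataset))

  if ("diversity" %in% config$analyses) {
    div <- diversity_summary(dataset, groups = config$parthenogens,
                             g = config$g)
    utils::write.table(div, file.path(out_dir, "diversity.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    note("diversity: %d groups, rarefaction g=%d", nrow(div), attr(div, "g"))
    results$diversity <- div
  }

  if ("shared" %in% config$analyses) {
    sp <- config$parthenogens
    pairs <- utils::combn(sp, 2, simplify = FALSE)
    shared <- do.call(rbind, lapply(pairs, function(pr) {
      data.frame(groupA = pr[1], groupB = pr[2],
                 shared_alleles = group_shared_alleles(dataset, pr[1], pr[2]),
                 k1 = shared_klocus_genotype_proportion(dataset, pr[1], pr[2], 1L),
                 k2 = shared_klocus_genotype_proportion(dataset, pr[1], pr[2], 2L),
                 max_shared_loci = max_shared_loci(dataset, pr[1], pr[2])$max,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(shared, file.path(out_dir, "shared_alleles.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    note("shared: %d pairs", nrow(shared))
    results$shared <- shared

    disc <- find_shared_multilocus_genotypes(dataset, groups = sp,
                                             min_freq = config$min_freq,
                                             max_loci = config$max_loci)
    utils::write.table(disc, file.path(out_dir, "shared_genotypes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    note("shared genotypes discovered: %d (subsets examined up to %d loci)",
         nrow(disc), config$max_loci)
    results$shared_genotypes <- disc
  }

  if ("coincidence" %in% config$analyses &&
      !is.null(results$shared_genotypes) && nrow(results$shared_genotypes)) {
    freqs <- allele_frequencies(dataset)
    pooled_pat <- pool_groups(freqs[config$paternal], weights = "by_sample",
                              group = "paternal_pooled")
    coin <- lapply(seq_len(nrow(results$shared_genotypes)), function(i) {
      row <- results$shared_genotypes[i, ]
      gt <- parse_genotype(gsub(";", ",", row$genotype, fixed = TRUE))
      carriers <- strsplit(row$groups, ",", fixed = TRUE)[[1]]
      pairs <- lapply(carriers, function(sp) {
        list(paternal = pooled_pat, maternal = freqs[[config$maternal[[sp]]]])
      })
      res <- if (length(pairs) >= 2L) {
        coincidence_prob(gt, pairs[seq_len(min(3L, length(pairs)))],
                         hom_mode = config$hom_mode)
      } else NULL
      list(genotype = row$genotype, groups = row$groups,
           freqs = row$freqs, n_loci = row$n_loci,
           zygosity = row$zygosity,
           coincidence_prob = if (is.null(res)) NA else res$coincidence_prob,
           n_zero_frequency_alleles = if (is.null(res)) NA else
             nrow(res$zero_frequency))
    })
    jsonlite::write_json(coin, file.path(out_dir, "coincidence.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note("coincidence: %d genotypes evaluated, hom_mode=%s", length(coin),
         config$hom_mode)
    results$coincidence <- coin
  }

  if ("networks" %in% config$analyses) {
    pds <- subset_group(dataset, config$parthenogens)
    bd <- bruvo_distance_matrix(pds)
    write_distance_matrix(bd$matrix, file.path(out_dir, "bruvo_matrix.tsv"))
    note("bruvo matrix: %d individuals, %d undefined pairs",
         nrow(bd$matrix), nrow(bd$undefined_pairs))
    msn <- minimum_spanning_network(pds)
    utils::write.table(msn$edges, file.path(out_dir, "msn_edges.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    gml_path <- file.path(out_dir, "msn.gml")
    igraph::write_graph(msn$graph, gml_path, format = "gml")
    # igraph stamps a Creator line with a timestamp; drop it so reruns are
    # byte-identical
    gml <- readLines(gml_path)
    writeLines(gml[!startsWith(gml, "Creator")], gml_path)
    note("msn: %d nodes, %d edges", nrow(msn$nodes), nrow(msn$edges))
    results$msn <- msn
    if (!anyNA(bd$matrix) && nrow(bd$matrix) >= 3L) {
      tr <- nj_tree(bd$matrix)
      ape::write.tree(tr, file.path(out_dir, "nj_bruvo.nwk"))
      note("nj tree written (%d tips)", length(tr$tip.label))
      results$nj <- tr
    } else {
      note("nj tree skipped: undefined pairwise distances present")
    }
    results$bruvo <- bd
  }

  manifest <- list(
    package = "msatclones",
    version = as.character(utils::packageVersion("msatclones")),
    seed = config$seed,
    config_hash = config_hash(config),
    config = unclass(config),
    n_individuals = nrow(dataset$geno),
    n_loci = nrow(dataset$loci),
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(results)
}
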