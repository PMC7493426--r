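# Bruvo distances, minimum spanning networks, NJ trees, shared-locus
# distance.

#' Bruvo distance between two microsatellite alleles
#'
#' `d = 1 - 2^(-|x|)` where `x` is the signed repeat-unit difference
#' between the alleles. Zero for identical alleles, approaching 1 as the
#' repeat difference grows; sign-invariant.
#'
#' @param x integer vector of repeat-unit differences.
#' @return distances in `[0, 1)`.
#' @export
bruvo_allele_distance <- function(x) {
  1 - 2^(-abs(x))
}

# Diploid per-locus Bruvo distance between unordered pairs of repeat
# counts: minimum over the two one-to-one allele pairings of the mean of
# the two allele distances.
bruvo_locus_distance <- function(ra, rb) {
  d11 <- bruvo_allele_distance(ra[1] - rb[1])
  d22 <- bruvo_allele_distance(ra[2] - rb[2])
  d12 <- bruvo_allele_distance(ra[1] - rb[2])
  d21 <- bruvo_allele_distance(ra[2] - rb[1])
  min((d11 + d22) / 2, (d12 + d21) / 2)
}

#' Bruvo distance between two diploid multilocus genotypes
#'
#' Allele sizes are converted to repeat counts per locus via
#' [to_repeat_units()]; at each locus scored in both genotypes the diploid
#' distance is the minimum over the two one-to-one allele pairings of the
#' mean allele distance, and the genotype distance is the mean over
#' commonly scored loci (pairwise deletion).
#'
#' @param callsA,callsB named lists (locus -> integer allele pair, `NULL`
#'   or `NA` for missing).
#' @param loci a [locus_table()] covering the loci.
#' @return the mean distance in `[0, 1]`, or `NA` (flagged undefined) when
#'   the genotypes share no scored locus.
#' @export
bruvo_genotype_distance <- function(callsA, callsB, loci) {
  vals <- numeric(0)
  for (i in seq_len(nrow(loci))) {
    l <- loci$name[i]
    a <- callsA[[l]]; b <- callsB[[l]]
    if (is.null(a) || is.null(b) || anyNA(a) || anyNA(b)) next
    ra <- to_repeat_units(a, loci[i, ])
    rb <- to_repeat_units(b, loci[i, ])
    vals <- c(vals, bruvo_locus_distance(ra, rb))
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Pairwise Bruvo distance matrix
#'
#' @param dataset a [genotype_dataset()].
#' @return list with `matrix` (symmetric, zero diagonal, labelled by
#'   individual id; `NA` marks pairs with no commonly scored locus) and
#'   `undefined_pairs` (two-column matrix of such label pairs).
#' @export
bruvo_distance_matrix <- function(dataset) {
  loci <- dataset$loci
  n <- nrow(dataset$geno)
  ids <- dataset$geno$id
  # precompute repeat counts: individuals x loci x 2
  r1 <- allele_matrix(dataset, 1L)
  r2 <- allele_matrix(dataset, 2L)
  for (i in seq_len(nrow(loci))) {
    l <- loci$name[i]
    ok <- !is.na(r1[, l])
    if (any(ok)) {
      r1[ok, l] <- to_repeat_units(r1[ok, l], loci[i, ])
      r2[ok, l] <- to_repeat_units(r2[ok, l], loci[i, ])
    }
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      common <- which(!is.na(r1[i, ]) & !is.na(r1[j, ]))
      if (length(common) == 0L) {
        D[i, j] <- D[j, i] <- NA_real_
        next
      }
      d <- vapply(common, function(k) {
        bruvo_locus_distance(c(r1[i, k], r2[i, k]), c(r1[j, k], r2[j, k]))
      }, numeric(1))
      D[i, j] <- D[j, i] <- mean(d)
    }
  }
  und <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
  undefined_pairs <- cbind(ids[und[, 1]], ids[und[, 2]])
  list(matrix = D, undefined_pairs = undefined_pairs)
}

#' Shared-locus distance between individuals
#'
#' Distance = `L - s`, where `L` is the total number of loci and `s` the
#' count of loci at which the two individuals carry the identical complete
#' unordered diploid genotype; loci missing in either individual never
#' count as shared.
#'
#' @param dataset a [genotype_dataset()].
#' @return symmetric integer matrix labelled by individual id.
#' @export
shared_locus_distance_matrix <- function(dataset) {
  L <- nrow(dataset$loci)
  a1 <- allele_matrix(dataset, 1L)
  a2 <- allele_matrix(dataset, 2L)
  key <- matrix(paste0(a1, "/", a2), nrow = nrow(a1))
  key[is.na(a1)] <- NA
  n <- nrow(key)
  D <- matrix(0L, n, n, dimnames = list(dataset$geno$id, dataset$geno$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sum(!is.na(key[i, ]) & !is.na(key[j, ]) & key[i, ] == key[j, ])
      D[i, j] <- D[j, i] <- L - s
    }
  }
  D
}

#' Minimum spanning network over collapsed genotypes
#'
#' Collapses individuals to unique multilocus genotypes (node multiplicity
#' = individual count), builds a minimum spanning tree on the distance
#' matrix, and additionally retains every non-tree edge whose weight ties —
#' within relative tolerance `tie_tol` — the maximum-weight edge on the MST
#' path it would short-circuit, so equally good alternative connections are
#' kept. Disconnected inputs (NA distances splitting the graph) are
#' returned as separate flagged components.
#'
#' @param dataset a [genotype_dataset()]; nodes are unique genotypes
#'   (individuals with missing data collapse only with identical keys).
#' @param distance `"bruvo"` or `"shared_locus"`.
#' @param tie_tol relative tie tolerance (default 1e-9).
#' @return list with `nodes` (data.frame: key, label of a representative
#'   individual, group, multiplicity), `edges` (data.frame: from, to,
#'   weight, in_mst), and `graph` (an igraph object of the retained edges).
#' @export
minimum_spanning_network <- function(dataset, distance = c("bruvo", "shared_locus"),
                                     tie_tol = 1e-9) {
  distance <- match.arg(distance)
  keys <- genotype_keys(dataset)
  reps <- match(unique(keys), keys)
  nodes <- data.frame(
    key = keys[reps],
    label = dataset$geno$id[reps],
    group = dataset$geno$species[reps],
    multiplicity = as.integer(table(keys)[keys[reps]]),
    stringsAsFactors = FALSE
  )
  ord <- order(nodes$key)  # deterministic node ordering
  nodes <- nodes[ord, , drop = FALSE]
  rownames(nodes) <- NULL
  sub <- dataset
  sub$geno <- dataset$geno[reps[ord], , drop = FALSE]
  D <- if (distance == "bruvo") bruvo_distance_matrix(sub)$matrix else
    shared_locus_distance_matrix(sub)
  dimnames(D) <- list(nodes$label, nodes$label)
  msn_from_matrix(D, nodes, tie_tol)
}

#' Minimum spanning network from a precomputed distance matrix
#'
#' Same construction as [minimum_spanning_network()] but starting from any
#' labelled symmetric distance matrix (one node per label, multiplicity 1
#' unless supplied).
#'
#' @param D labelled symmetric distance matrix; `NA` marks undefined pairs.
#' @param tie_tol relative tie tolerance.
#' @param multiplicity optional named integer vector of node weights.
#' @param group optional named character vector of node group labels.
#' @return as [minimum_spanning_network()].
#' @export
msn_from_distances <- function(D, tie_tol = 1e-9, multiplicity = NULL,
                               group = NULL) {
  labs <- rownames(D)
  nodes <- data.frame(
    key = labs, label = labs,
    group = if (is.null(group)) NA_character_ else unname(group[labs]),
    multiplicity = if (is.null(multiplicity)) 1L else
      as.integer(unname(multiplicity[labs])),
    stringsAsFactors = FALSE)
  msn_from_matrix(D, nodes, tie_tol)
}

# Core MSN construction from a labelled distance matrix.
msn_from_matrix <- function(D, nodes, tie_tol = 1e-9) {
  n <- nrow(D)
  adj <- !is.na(D)
  diag(adj) <- FALSE
  gfull <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::E(gfull)$weight <- D[igraph::as_edgelist(gfull, names = FALSE)]
  comp <- igraph::components(gfull)
  edge_rows <- list()
  for (cid in seq_len(comp$no)) {
    vs <- which(comp$membership == cid)
    if (length(vs) < 2L) next
    sub <- igraph::induced_subgraph(gfull, vs)
    mst <- igraph::mst(sub, algorithm = "prim")
    el <- igraph::as_edgelist(mst)
    w <- igraph::E(mst)$weight
    mst_rows <- data.frame(from = el[, 1], to = el[, 2], weight = w,
                           in_mst = TRUE, component = cid,
                           stringsAsFactors = FALSE)
    # tie retention: keep non-tree edge (u,v) iff its weight ties the
    # cycle-max, i.e. the largest MST-path edge between u and v
    el_all <- igraph::as_edgelist(sub)
    w_all <- igraph::E(sub)$weight
    in_tree <- paste(pmin(el_all[, 1], el_all[, 2]),
                     pmax(el_all[, 1], el_all[, 2])) %in%
      paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    extra <- list()
    for (k in which(!in_tree)) {
      u <- el_all[k, 1]; v <- el_all[k, 2]
      path <- igraph::shortest_paths(mst, from = u, to = v,
                                     output = "epath")$epath[[1]]
      cyc_max <- max(igraph::E(mst)$weight[as.integer(path)])
      if (w_all[k] <= cyc_max * (1 + tie_tol) + tie_tol) {
        extra[[length(extra) + 1L]] <- data.frame(
          from = u, to = v, weight = w_all[k], in_mst = FALSE,
          component = cid, stringsAsFactors = FALSE)
      }
    }
    edge_rows[[cid]] <- rbind(mst_rows, do.call(rbind, extra))
  }
  edges <- do.call(rbind, edge_rows)
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), in_mst = logical(0),
                        component = integer(0))
  }
  # canonical edge order for reproducibility
  a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
  edges$from <- a; edges$to <- b
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "weight")], directed = FALSE,
    vertices = nodes[, c("label", "group", "multiplicity")])
  list(nodes = nodes, edges = edges, graph = g,
       n_components = max(1L, length(edge_rows)))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via \pkg{ape}), with negative
#' branch lengths clamped to zero and the deficit shifted onto the adjacent
#' sister branch so path lengths between tips are preserved.
#'
#' @param D symmetric labelled distance matrix with finite entries.
#' @return an unrooted `phylo` object (serialize with [ape::write.tree()]).
#' @export
nj_tree <- function(D) {
  if (anyNA(D)) {
    stop("distance matrix has undefined entries; impute or drop individuals ",
         "with no commonly scored loci before tree building")
  }
  if (nrow(D) < 3L) stop("need at least 3 labels for neighbor joining")
  tr <- ape::nj(as.dist(D))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sibs) > 0) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + deficit
    }
    tr$edge.length[e] <- 0
  }
  tr
}

#' Write a distance matrix
#'
#' @param D labelled symmetric matrix.
#' @param path output path.
#' @param format `"tsv"` (square, with row names) or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(D, path, sep = "\t", quote = FALSE, col.names = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(D)), con)
    for (i in seq_len(nrow(D))) {
      writeLines(paste(formatC(rownames(D)[i], width = -10),
                       paste(sprintf("%.6f", D[i, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}
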