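## Module detection: average-linkage clustering of the consensus TOM
## dissimilarity with adaptive branch pruning, grey = unassigned.

## Conventional module color sequence (largest module first).
standard_module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "sienna3",
  "yellowgreen", "skyblue3", "plum1", "orangered4", "mediumpurple3",
  "lightsteelblue1", "lightcyan1", "ivory", "floralwhite", "darkorange2",
  "brown4", "bisque4", "darkslateblue", "plum2", "thistle2", "thistle1",
  "salmon4", "palevioletred3", "navajowhite2", "maroon", "lightpink4",
  "lavenderblush3", "honeydew1", "darkseagreen4", "coral1")

#' Detect co-expression modules by adaptive dendrogram branch pruning
#'
#' Genes are clustered by average-linkage hierarchical clustering of the
#' consensus TOM dissimilarity. In such a dissimilarity matrix the unrelated
#' gene pairs pile up in a narrow high-dissimilarity band whose location
#' depends on the soft-threshold power, so no fixed cut height transfers
#' across networks. Detection is therefore scale-free in two stages:
#'
#' 1. *Branch scan.* Every possible cut height of the dendrogram is scored
#'    by the number of branches holding at least `min_module_size` genes,
#'    and the lowest cut height attaining the maximum is taken. This
#'    isolates the tight branch cores wherever they sit on the height axis.
#' 2. *Completion.* Genes left outside a core are attached to the nearest
#'    core if their mean dissimilarity to it is below the midpoint between
#'    that core's mean internal dissimilarity and the unrelated-pair level
#'    (the median off-diagonal dissimilarity), recovering branch periphery
#'    without absorbing background genes.
#'
#' Genes in no surviving branch are left unassigned ("grey"). Modules are
#' labeled with the conventional color sequence in decreasing size order, so
#' "turquoise" is always the largest module.
#'
#' @param network A `gene_network` from [consensus_tom()].
#' @param min_module_size Minimum genes per module (default 30).
#' @param completion Run the completion stage (default TRUE).
#' @return Named character vector mapping each network gene to its module
#'   color ("grey" = unassigned), carrying the dendrogram as attribute
#'   `"dendrogram"`.
#' @export
detect_modules <- function(network, min_module_size = 30, completion = TRUE) {
  stopifnot(inherits(network, "gene_network"))
  check_scalar_number(min_module_size, "min_module_size", lower = 2,
                      integerish = TRUE)
  genes <- network$gene_ids
  n <- length(genes)
  if (n < min_module_size) {
    warning("fewer genes than min_module_size; all genes left unassigned")
    return(stats::setNames(rep("grey", n), genes))
  }
  d <- network$consensus_dissimilarity
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cores <- branch_scan(hc, min_module_size)
  labels <- rep("grey", n)
  if (length(cores)) {
    cores <- prune_cores(cores, d, min_module_size)
    if (completion) cores <- complete_branches(cores, d)
    ord <- order(-lengths(cores), vapply(cores, min, 0L))
    cores <- cores[ord]
    colors <- c(standard_module_colors,
                sprintf("module%d", seq_len(max(0, length(cores) -
                  length(standard_module_colors)))))
    for (i in seq_along(cores)) labels[cores[[i]]] <- colors[i]
  }
  structure(stats::setNames(labels, genes), dendrogram = hc)
}

## Scan all cut heights of the dendrogram by replaying its merges; return
## the partition (as a list of leaf-index vectors, only clusters >= min_size)
## with the most clusters of at least min_size, at the lowest such height.
branch_scan <- function(hc, min_size) {
  n <- length(hc$order)
  n_nodes <- nrow(hc$merge)
  cluster_of_node <- integer(n_nodes)    # union-find over merge replay
  size <- rep(1L, n + n_nodes)           # leaves 1..n, nodes n+1..n+n_nodes
  count <- 0L                            # clusters >= min_size
  best_count <- if (n >= min_size) 0L else -1L   # cut above root = 1 cluster
  best_merge <- NA_integer_
  for (i in seq_len(n_nodes)) {
    ch <- hc$merge[i, ]
    s <- vapply(ch, function(x) if (x < 0) 1L else size[n + x], 0L)
    tot <- sum(s)
    size[n + i] <- tot
    count <- count - sum(s >= min_size) + (tot >= min_size)
    if (count > best_count) {
      best_count <- count
      best_merge <- i
    }
  }
  if (best_count < 1L) return(list())
  ## materialize the partition right after merge `best_merge`
  leaf_sets <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    ch <- hc$merge[i, ]
    get <- function(x) if (x < 0) -x else leaf_sets[[x]]
    leaf_sets[[i]] <- c(get(ch[1L]), get(ch[2L]))
  }
  merged_away <- unique(hc$merge[seq_len(best_merge), ])
  merged_away <- merged_away[merged_away > 0]
  live <- setdiff(seq_len(best_merge), merged_away)
  clusters <- leaf_sets[live]
  clusters[lengths(clusters) >= min_size]
}

## Drop core members whose mean dissimilarity to the rest of the core sits
## at the background level (late-joining hitchhikers on a tight branch);
## cores falling below min_size are dismissed entirely.
prune_cores <- function(cores, d, min_size, theta = 0.25) {
  background <- stats::median(d[lower.tri(d)])
  cores <- lapply(cores, function(idx) {
    s <- length(idx)
    within <- sum(d[idx, idx]) / (s * (s - 1))
    depth <- background - within
    if (depth <= 0) return(integer())
    member_mean <- (colSums(d[idx, idx])) / (s - 1)
    idx[background - member_mean >= theta * depth]
  })
  cores[lengths(cores) >= min_size]
}

## Attach unassigned genes to the closest branch core when clearly closer
## than the background dissimilarity level. The margin is relative: a gene
## joins a core when it closes at least `theta` of the distance between the
## background level and the core's internal dissimilarity.
complete_branches <- function(cores, d, theta = 0.25) {
  assigned <- unlist(cores)
  free <- setdiff(seq_len(nrow(d)), assigned)
  if (!length(free)) return(cores)
  background <- stats::median(d[lower.tri(d)])
  within <- vapply(cores, function(idx) {
    s <- length(idx)
    sum(d[idx, idx]) / (s * (s - 1))
  }, 0)
  mean_to_core <- vapply(cores, function(idx)
    colMeans(d[idx, free, drop = FALSE]), numeric(length(free)))
  mean_to_core <- matrix(mean_to_core, nrow = length(free))
  nearest <- max.col(-mean_to_core, ties.method = "first")
  depth <- background - within[nearest]
  margin <- background - mean_to_core[cbind(seq_along(free), nearest)]
  ok <- depth > 0 & margin >= theta * depth
  for (j in which(ok))
    cores[[nearest[j]]] <- c(cores[[nearest[j]]], free[j])
  cores
}
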