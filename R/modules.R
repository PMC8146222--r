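## Module detection: average-linkage clustering of the TOM dissimilarity,
## a tree-variant dynamic cut, module eigengenes, and eigengene-based
## merging of correlated modules.

#' Average-linkage clustering of a dissimilarity matrix
#'
#' @param diss Square symmetric dissimilarity matrix with zero diagonal
#'   (typically `1 - TOM`).
#' @return An [stats::hclust] object (average linkage).
#' @export
hierarchical_cluster <- function(diss) {
  if (!isSymmetric(unname(diss), tol = 1e-8))
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  stats::hclust(stats::as.dist(diss), method = "average")
}

## Per-node bookkeeping for an hclust tree: children of merge row i always
## have smaller row index, so sizes/heights can be accumulated in one pass.
.tree_info <- function(hc) {
  n <- length(hc$height) + 1L
  size <- integer(n - 1L)
  for (i in seq_len(n - 1L)) {
    ch <- hc$merge[i, ]
    size[i] <- sum(ifelse(ch < 0, 1L, size[pmax(ch, 1L)]))
  }
  leaves <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    ch <- hc$merge[i, ]
    leaves[[i]] <- c(
      if (ch[1] < 0) -ch[1] else leaves[[ch[1]]],
      if (ch[2] < 0) -ch[2] else leaves[[ch[2]]]
    )
  }
  list(size = size, leaves = leaves)
}

#' Dynamic tree cut (tree variant)
#'
#' Top-down adaptive branch decomposition of an average-linkage dendrogram.
#' The tree is first cut at `cut_height_fraction` of the maximal merge
#' height; each resulting branch is then decomposed recursively: a branch
#' splits into its two children when both would retain at least
#' `min_module_size` leaves and the drop from the branch's merge height to
#' its children's is at least `gap_fraction` of the branch height (the
#' branch-sensitivity default). An accepted branch is then trimmed along
#' its spine: leaves and small side-branches that join the branch above its
#' largest relative height gap (again `gap_fraction` of the joining height)
#' are stragglers without genuine co-expression with the core and go grey.
#' Accepted cores with at least `min_module_size` leaves become modules;
#' all remaining leaves are assigned to the reserved `"grey"` label.
#' Modules are labelled `M1` (largest) .. `Mk` (smallest).
#'
#' @param dendro An [stats::hclust] object.
#' @param min_module_size Minimum module size (default 30).
#' @param cut_height_fraction Static cut as a fraction of the maximum merge
#'   height (default 0.99).
#' @param gap_fraction Branch-sensitivity: minimum relative height drop for
#'   a within-branch split (default 0.1).
#' @return Named character vector gene -> module label (`"grey"` for
#'   unassigned genes).
#' @export
dynamic_tree_cut <- function(dendro, min_module_size = 30,
                             cut_height_fraction = 0.99,
                             gap_fraction = 0.1) {
  stopifnot(inherits(dendro, "hclust"))
  if (min_module_size < 2) stop("min_module_size must be >= 2", call. = FALSE)
  n <- length(dendro$height) + 1L
  labels <- dendro$labels
  if (is.null(labels)) labels <- as.character(seq_len(n))
  assignment <- rep("grey", n)
  names(assignment) <- labels
  if (min_module_size > n) {
    warning("min_module_size exceeds the number of genes; all genes grey")
    return(assignment)
  }
  info <- .tree_info(dendro)
  h_cut <- cut_height_fraction * max(dendro$height)
  node_h <- function(node) if (node < 0) 0 else dendro$height[node]
  node_size <- function(node) if (node < 0) 1L else info$size[node]

  # walk the branch spine (always into the larger child while the smaller
  # one is sub-module-size) and cut at the largest relative height gap;
  # everything joining above the gap is a straggler, the core continues
  trim_spine <- function(node) {
    repeat {
      spine <- node
      cur <- node
      repeat {
        if (cur < 0) break
        ch <- dendro$merge[cur, ]
        s1 <- node_size(ch[1]); s2 <- node_size(ch[2])
        big <- if (s1 >= s2) ch[1] else ch[2]
        small <- if (s1 >= s2) ch[2] else ch[1]
        if (node_size(small) >= min_module_size ||
            node_size(big) < min_module_size) break
        spine <- c(spine, big)
        cur <- big
      }
      if (length(spine) < 2L) return(node)
      hs <- vapply(spine, node_h, numeric(1))
      gaps <- hs[-length(hs)] - hs[-1]
      rel_ok <- gaps >= gap_fraction * hs[-length(hs)]
      if (!any(rel_ok)) return(node)
      best <- which(gaps == max(gaps[rel_ok]) & rel_ok)[1L]
      node <- spine[best + 1L]
      if (node < 0) return(node)
    }
  }

  modules <- list()
  stack <- list(n - 1L)           # root merge
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (node < 0) next            # singleton leaf stays grey
    ch <- dendro$merge[node, ]
    h <- node_h(node)
    split_forced <- h > h_cut
    split_gap <- node_size(ch[1]) >= min_module_size &&
      node_size(ch[2]) >= min_module_size &&
      (h - max(node_h(ch[1]), node_h(ch[2]))) >= gap_fraction * h
    if (split_forced || split_gap) {
      stack <- c(stack, list(ch[1], ch[2]))
    } else if (info$size[node] >= min_module_size) {
      core <- trim_spine(node)
      if (core > 0 && info$size[core] >= min_module_size)
        modules[[length(modules) + 1L]] <- info$leaves[[core]]
    }                              # else: too small, leaves stay grey
  }
  if (length(modules)) {
    ord <- order(vapply(modules, length, integer(1)), decreasing = TRUE)
    for (i in seq_along(ord))
      assignment[modules[[ord[i]]]] <- paste0("M", i)
  }
  assignment
}

#' Module eigengene
#'
#' First principal component of the module's gene x sample matrix after
#' per-gene standardization (mean 0, sd 1 across samples). The returned
#' score vector has unit norm and is oriented so it correlates
#' non-negatively with the members' mean standardized profile; when that
#' correlation is exactly zero (or undefined), the first sample's score is
#' made non-negative.
#'
#' @param logmat Log-expression matrix containing the member genes.
#' @param members Character vector of member gene ids.
#' @return List with `scores` (named per-sample vector, unit norm) and
#'   `variance_explained` in `[0, 1]`.
#' @export
module_eigengene <- function(logmat, members) {
  if (!length(members)) stop("empty module", call. = FALSE)
  if (ncol(logmat) < 2L) stop("need >= 2 samples", call. = FALSE)
  miss <- setdiff(members, rownames(logmat))
  if (length(miss))
    stop("member gene(s) absent from matrix: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  x <- logmat[members, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0))
    stop("all-constant member profile(s): ",
         paste(utils::head(members[sds == 0], 5), collapse = ", "),
         call. = FALSE)
  z <- (x - rowMeans(x)) / sds
  sv <- svd(z)
  scores <- sv$v[, 1L]
  mean_prof <- colMeans(z)
  orient <- sum(scores * mean_prof)
  if (orient < 0) scores <- -scores
  if (orient == 0 && scores[1L] < 0) scores <- -scores
  names(scores) <- colnames(logmat)
  list(scores = scores,
       variance_explained = sv$d[1L]^2 / sum(sv$d^2))
}

#' Eigengenes of all non-grey modules
#'
#' @param logmat Log-expression matrix.
#' @param assignment Named module-label vector.
#' @param grey_label Unassigned label (default `"grey"`).
#' @return Sample x module matrix of eigengene scores.
#' @export
module_eigengenes <- function(logmat, assignment, grey_label = "grey") {
  mods <- setdiff(sort(unique(assignment)), grey_label)
  if (!length(mods)) stop("no non-grey modules", call. = FALSE)
  sapply(mods, function(m)
    module_eigengene(logmat, names(assignment)[assignment == m])$scores)
}

#' Merge modules with correlated eigengenes
#'
#' Greedy highest-correlation-first merging: while any pair of non-grey
#' eigengenes correlates at or above `cor_threshold`, the most correlated
#' pair is merged (ties broken by smaller combined size, then lexicographic
#' label) and all eigengenes recomputed. Grey never merges. Labels are
#' re-ranked by size (`M1` largest) at the end, so the post-merge guarantee
#' holds: no final pair of eigengenes correlates at `cor_threshold` or more.
#'
#' @param logmat Log-expression matrix.
#' @param assignment Named module-label vector.
#' @param cor_threshold Eigengene correlation needed to merge (default 0.85).
#' @param grey_label Unassigned label.
#' @return Named module-label vector after merging, size-ranked labels.
#' @export
merge_modules <- function(logmat, assignment, cor_threshold = 0.85,
                          grey_label = "grey") {
  asg <- assignment
  repeat {
    mods <- setdiff(sort(unique(asg)), grey_label)
    if (length(mods) < 2L) break
    eg <- module_eigengenes(logmat, asg, grey_label)
    cc <- stats::cor(eg)
    diag(cc) <- -Inf
    best <- max(cc)
    if (best < cor_threshold) break
    idx <- which(cc == best, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    if (nrow(idx) > 1L) {           # tie-break: smaller combined module first
      sizes <- table(asg)
      comb <- sizes[colnames(cc)[idx[, 1]]] + sizes[colnames(cc)[idx[, 2]]]
      key <- paste(colnames(cc)[idx[, 1]], colnames(cc)[idx[, 2]])
      idx <- idx[order(comb, key)[1L], , drop = FALSE]
    }
    a <- colnames(cc)[idx[1, 1]]
    b <- colnames(cc)[idx[1, 2]]
    keep <- if (sum(asg == a) >= sum(asg == b)) a else b
    asg[asg %in% c(a, b)] <- keep
  }
  relabel_by_size(asg, grey_label)
}

#' Re-rank module labels by size
#'
#' @param assignment Named module-label vector.
#' @param grey_label Unassigned label, kept as-is.
#' @return Assignment with modules relabelled `M1` (largest) .. `Mk`
#'   (smallest); size ties broken by previous label order.
#' @export
relabel_by_size <- function(assignment, grey_label = "grey") {
  mods <- setdiff(sort(unique(assignment)), grey_label)
  if (!length(mods)) return(assignment)
  sizes <- vapply(mods, function(m) sum(assignment == m), integer(1))
  ord <- mods[order(-sizes, mods)]
  map <- stats::setNames(paste0("M", seq_along(ord)), ord)
  out <- assignment
  nz <- assignment != grey_label
  out[nz] <- map[assignment[nz]]
  out
}

#' Write a module assignment as two-column TSV
#'
#' @param assignment Named module-label vector.
#' @param path Output path.
#' @param comment Optional `#` header lines.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  writeLines("gene_id\tmodule", con)
  writeLines(paste(names(assignment), assignment, sep = "\t"), con)
  invisible(path)
}
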