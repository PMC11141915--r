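## Multiregion driver phylogeny from binary mutation presence patterns
##
## Mutations retained by the VAF/annotation filter define, per patient, a
## presence pattern over samples. Laminar (nested or disjoint) pattern
## families admit a containment tree: each pattern becomes a branch whose
## length is the number of mutations sharing it, samples hang as leaves under
## the smallest pattern containing them, and the all-sample pattern is the
## trunk (MRCA). Crossing patterns are resolved by iteratively dropping the
## cheapest conflicting pattern.

#' Group filtered mutations into presence patterns
#'
#' @param presence named list (by sample id) of filtered variant tables, or a
#'   logical mutation x sample matrix with mutation ids as rownames
#' @return data.frame `pattern` (comma-joined sorted sample ids), `count`,
#'   `drivers` (comma-joined driver labels in the pattern), `samples` (list
#'   column of sample id vectors), ordered by pattern size descending then
#'   lexically
#' @export
build_pattern_matrix <- function(presence) {
  if (is.list(presence) && !is.data.frame(presence)) {
    samples <- names(presence)
    ids <- unique(unlist(lapply(presence, function(v) v$id)))
    for (s in samples) {
      if (anyDuplicated(presence[[s]]$id))
        stop("duplicate mutation id in sample ", s, ": ",
             presence[[s]]$id[duplicated(presence[[s]]$id)][1])
    }
    mat <- vapply(samples, function(s) ids %in% presence[[s]]$id,
                  logical(length(ids)))
    mat <- matrix(mat, nrow = length(ids),
                  dimnames = list(ids, samples))
    drv <- stats::setNames(rep(NA_character_, length(ids)), ids)
    for (s in samples) {
      v <- presence[[s]]
      if ("driver" %in% names(v)) {
        hit <- !is.na(v$driver)
        drv[v$id[hit]] <- v$driver[hit]
      }
    }
  } else {
    mat <- as.matrix(presence)
    if (anyDuplicated(rownames(mat))) stop("duplicate mutation id: ",
                                           rownames(mat)[duplicated(rownames(mat))][1])
    drv <- stats::setNames(rep(NA_character_, nrow(mat)), rownames(mat))
  }
  if (ncol(mat) < 2) stop("need >= 2 samples to build patterns")
  keep <- rowSums(mat) > 0
  mat <- mat[keep, , drop = FALSE]; drv <- drv[keep]
  if (!nrow(mat))
    return(data.frame(pattern = character(0), count = integer(0),
                      drivers = character(0), stringsAsFactors = FALSE))
  pat <- apply(mat, 1, function(r) paste(sort(colnames(mat)[r]), collapse = ","))
  agg <- lapply(split(seq_along(pat), pat), function(i) {
    d <- drv[i]; d <- d[!is.na(d)]
    data.frame(pattern = pat[i[1]], count = length(i),
               drivers = paste(sort(unique(d)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  size <- lengths(strsplit(out$pattern, ","))
  out <- out[order(-size, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out$samples <- strsplit(out$pattern, ",")
  out
}

#' Pairwise containment conflicts among patterns
#'
#' Two binary patterns conflict when they overlap without one containing the
#' other — the condition under which no containment tree exists.
#'
#' @param patterns output of [build_pattern_matrix()]
#' @return data.frame `pattern1`, `pattern2`, one row per conflicting pair
#' @export
check_compatibility <- function(patterns) {
  n <- nrow(patterns)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- patterns$samples[[i]]; b <- patterns$samples[[j]]
      inter <- length(intersect(a, b))
      if (inter > 0 && inter < length(a) && inter < length(b))
        out[[length(out) + 1L]] <- data.frame(pattern1 = patterns$pattern[i],
                                              pattern2 = patterns$pattern[j],
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(pattern1 = character(0), pattern2 = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Build a rooted clone tree from mutation patterns
#'
#' Constructs the containment (Hasse) tree over the pattern family. When
#' patterns conflict, policy `"drop-min"` iteratively removes the conflicting
#' pattern with the fewest mutations (ties: the smaller pattern, then lexical
#' order) until the family is laminar; removals are recorded. The all-sample
#' pattern roots the tree and is created with count 0 if absent.
#'
#' @param patterns output of [build_pattern_matrix()]
#' @param metadata optional data.frame (`sample`, plus e.g. `subcategory`,
#'   `ploidy`, `metastasis`) attached to leaves
#' @param policy conflict resolution policy; only `"drop-min"` is defined
#' @return object of class `clone_tree`: list with `nodes` (data.frame `id`,
#'   `parent`, `length`, `type`, `pattern`, `drivers`, `sample`, leaf
#'   metadata columns), `dropped` (removed patterns), `labels` (annotation
#'   store)
#' @export
build_tree <- function(patterns, metadata = NULL, policy = "drop-min") {
  stopifnot(policy == "drop-min")
  pats <- patterns
  dropped <- pats[0, , drop = FALSE]
  repeat {
    conf <- check_compatibility(pats)
    if (!nrow(conf)) break
    inplay <- unique(c(conf$pattern1, conf$pattern2))
    cand <- pats[pats$pattern %in% inplay, , drop = FALSE]
    sz <- lengths(cand$samples)
    ord <- order(cand$count, sz, cand$pattern)
    victim <- cand$pattern[ord[1]]
    dropped <- rbind(dropped, pats[pats$pattern == victim, , drop = FALSE])
    pats <- pats[pats$pattern != victim, , drop = FALSE]
    if (!nrow(pats)) break
  }
  all_samples <- sort(unique(unlist(patterns$samples)))
  if (length(all_samples) < 2) warning("single-sample patient: degenerate tree")
  root_pat <- paste(all_samples, collapse = ",")
  if (!root_pat %in% pats$pattern) {
    pats <- rbind(data.frame(pattern = root_pat, count = 0L, drivers = "",
                             samples = I(list(all_samples)),
                             stringsAsFactors = FALSE), pats)
  }
  sz <- lengths(pats$samples)
  pats <- pats[order(-sz, pats$pattern), , drop = FALSE]

  ## Hasse parent: the smallest strict superset
  parent_of <- function(i) {
    a <- pats$samples[[i]]
    best <- NA_integer_; bestsz <- Inf
    for (j in seq_len(nrow(pats))) {
      if (j == i) next
      b <- pats$samples[[j]]
      if (length(b) > length(a) && all(a %in% b) && length(b) < bestsz) {
        best <- j; bestsz <- length(b)
      }
    }
    best
  }
  n <- nrow(pats)
  nodes <- data.frame(id = paste0("b", seq_len(n)),
                      parent = NA_character_,
                      length = pats$count, type = "branch",
                      pattern = pats$pattern, drivers = pats$drivers,
                      sample = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    p <- parent_of(i)
    nodes$parent[i] <- if (is.na(p)) NA_character_ else nodes$id[p]
  }
  ## leaves: each sample under the smallest pattern containing it
  leaf <- lapply(all_samples, function(s) {
    holders <- which(vapply(pats$samples, function(x) s %in% x, logical(1)))
    hsz <- lengths(pats$samples)[holders]
    at <- holders[which.min(hsz)]
    data.frame(id = paste0("leaf_", s), parent = nodes$id[at], length = 0,
               type = "leaf", pattern = s, drivers = "", sample = s,
               stringsAsFactors = FALSE)
  })
  nodes <- rbind(nodes, do.call(rbind, leaf))
  if (!is.null(metadata)) {
    mi <- match(nodes$sample, metadata$sample)
    for (col in setdiff(names(metadata), "sample")) {
      nodes[[col]] <- metadata[[col]][mi]
    }
  }
  structure(list(nodes = nodes, dropped = dropped,
                 labels = data.frame(node = character(0), label = character(0),
                                     stringsAsFactors = FALSE)),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  nl <- x$nodes[x$nodes$type == "leaf", ]
  cat("Clone tree:", nrow(nl), "samples,",
      sum(x$nodes$type == "branch"), "branches, total mutation length",
      sum(x$nodes$length), "\n")
  if (nrow(x$dropped))
    cat("  dropped by conflict policy:", paste(x$dropped$pattern, collapse = "; "), "\n")
  invisible(x)
}

#' Annotate tree branches with driver, copy-number and WGD events
#'
#' Driver mutations already sit on the branch of their pattern (carried from
#' [build_pattern_matrix()]). Sample-level events (arm losses/gains, WGD) are
#' placed on the deepest branch whose descendant samples all carry the event;
#' when the event's sample set is not exactly a clade, the deepest branch
#' whose clade is contained in the event set is used and a warning raised.
#'
#' @param tree `clone_tree`
#' @param events named list: label -> character vector of samples carrying
#'   the event (e.g. `list(WGD = c("R2"), "loss_17" = c("R1","R2"))`)
#' @return the tree with `labels` filled (`node`, `label`, `exact`)
#' @export
annotate_tree <- function(tree, events) {
  nodes <- tree$nodes
  clade <- function(id) {
    kids <- nodes$id[!is.na(nodes$parent) & nodes$parent == id]
    leaves <- nodes$sample[nodes$id == id]
    leaves <- leaves[!is.na(leaves)]
    c(leaves, unlist(lapply(kids, clade)))
  }
  branch_ids <- nodes$id[nodes$type == "branch"]
  clades <- lapply(branch_ids, clade)
  names(clades) <- branch_ids
  labs <- list()
  for (lab in names(events)) {
    ev <- sort(events[[lab]])
    exact <- vapply(clades, function(cl) identical(sort(cl), ev), logical(1))
    if (any(exact)) {
      sizes <- lengths(clades)[exact]
      node <- names(clades)[exact][which.min(sizes)]
      labs[[length(labs) + 1L]] <- data.frame(node = node, label = lab,
                                              exact = TRUE)
    } else {
      compat <- vapply(clades, function(cl) all(cl %in% ev) & length(cl) > 0,
                       logical(1))
      if (any(compat)) {
        sizes <- lengths(clades)[compat]
        node <- names(clades)[compat][which.max(sizes)]
        warning("event ", lab, " does not match a clade; attached to deepest ",
                "compatible branch")
        labs[[length(labs) + 1L]] <- data.frame(node = node, label = lab,
                                                exact = FALSE)
      } else {
        warning("event ", lab, " matches no branch; skipped")
      }
    }
  }
  tree$labels <- if (length(labs)) do.call(rbind, labs) else tree$labels
  tree
}

## Newick export / import ----------------------------------------------------

#' Export a clone tree to Newick
#'
#' Branch lengths are mutation counts; leaves carry sample ids. Attributes
#' (subcategory, ploidy, metastasis, branch labels) travel in a JSON sidecar
#' written by [write_tree()] so the Newick stays parseable by any reader.
#'
#' @param tree `clone_tree`
#' @return single Newick string (terminated by ";")
#' @export
export_newick <- function(tree) {
  nodes <- tree$nodes
  rec <- function(id) {
    kids <- nodes$id[!is.na(nodes$parent) & nodes$parent == id]
    me <- nodes[nodes$id == id, ]
    name <- if (me$type == "leaf") me$sample else ""
    if (!length(kids)) return(paste0(name, ":", me$length))
    inner <- paste(vapply(kids, rec, character(1)), collapse = ",")
    paste0("(", inner, ")", name, ":", me$length)
  }
  root <- nodes$id[is.na(nodes$parent)]
  paste0(rec(root), ";")
}

#' Write a clone tree (Newick + JSON attribute sidecar)
#'
#' @param tree `clone_tree`
#' @param path output Newick path; the sidecar goes to `<path>.json`
#' @return invisibly, the two paths
#' @export
write_tree <- function(tree, path) {
  writeLines(export_newick(tree), path)
  side <- paste0(path, ".json")
  jsonlite::write_json(list(nodes = tree$nodes[setdiff(names(tree$nodes), "samples")],
                            labels = tree$labels,
                            dropped = tree$dropped[setdiff(names(tree$dropped),
                                                           "samples")]),
                       side, dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(newick = path, sidecar = side))
}

#' Rooted Robinson-Foulds distance between two clone trees
#'
#' Counts clades (leaf sets under internal branches, excluding the trivial
#' all-leaf clade and singletons) present in one tree but not the other.
#'
#' @param tree1,tree2 `clone_tree` objects, or lists of character vectors of
#'   leaf sets
#' @return non-negative integer; 0 iff the clade sets coincide
#' @export
rf_rooted <- function(tree1, tree2) {
  clades_of <- function(tr) {
    if (inherits(tr, "clone_tree")) {
      nodes <- tr$nodes
      clade <- function(id) {
        kids <- nodes$id[!is.na(nodes$parent) & nodes$parent == id]
        leaves <- nodes$sample[nodes$id == id]
        leaves <- leaves[!is.na(leaves)]
        c(leaves, unlist(lapply(kids, clade)))
      }
      cl <- lapply(nodes$id[nodes$type == "branch"], clade)
    } else cl <- tr
    all_l <- sort(unique(unlist(cl)))
    cl <- lapply(cl, function(x) sort(unique(x)))
    cl <- cl[lengths(cl) > 1 & !vapply(cl, identical, logical(1), all_l)]
    unique(vapply(cl, paste, character(1), collapse = ","))
  }
  a <- clades_of(tree1); b <- clades_of(tree2)
  length(setdiff(a, b)) + length(setdiff(b, a))
}
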