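#' Graft family subtrees onto an ultrametric family backbone
#'
#' Each backbone tip named for a family is replaced by that family's
#' subtree; the subtree keeps its own (relative) branch lengths. A family
#' represented by a single OTU becomes one pendant branch of fixed length
#' appended to the backbone terminal edge. Families present in the backbone
#' but absent from `subtrees` are dropped with a warning.
#'
#' @param backbone [ape::phylo] with family names as tip labels.
#' @param subtrees named list (family -> [ape::phylo]); a single-OTU family
#'   may be given as a character OTU name or a 1-tip tree.
#' @param singleton_branch pendant branch length for single-OTU families;
#'   default is half the family's backbone terminal branch.
#' @param orders optional named character (family -> order) carried into the
#'   tip table.
#' @return a `calibrated_tree` over OTUs with per-tip family (and order).
#' @export
graft_subtrees <- function(backbone, subtrees, singleton_branch = NULL,
                           orders = NULL) {
  phy <- as_phylo(backbone)
  unknown <- setdiff(names(subtrees), phy$tip.label)
  if (length(unknown) > 0) {
    stop_classed("unknown_family", "subtree families not in backbone: %s",
                 paste(unknown, collapse = ", "))
  }
  absent <- setdiff(phy$tip.label, names(subtrees))
  if (length(absent) > 0) {
    warning(sprintf("families without subtrees dropped: %s",
                    paste(absent, collapse = ", ")), call. = FALSE)
    if (length(absent) == length(phy$tip.label)) {
      stop_classed("invalid_argument", "no families left after dropping")
    }
    phy <- ape::drop.tip(phy, absent)
  }
  fam_of_tip <- character(0)
  for (fam in names(subtrees)) {
    sub <- subtrees[[fam]]
    tip_idx <- which(phy$tip.label == fam)
    term_len <- phy$edge.length[phy$edge[, 2] == tip_idx]
    if (is.character(sub) || (inherits(sub, "phylo") && length(sub$tip.label) == 1L)) {
      otu <- if (is.character(sub)) sub else sub$tip.label
      L <- if (!is.null(singleton_branch)) singleton_branch else term_len / 2
      # a single pendant branch continues the terminal edge (no new node)
      phy$tip.label[tip_idx] <- otu
      phy$edge.length[phy$edge[, 2] == tip_idx] <-
        phy$edge.length[phy$edge[, 2] == tip_idx] + L
      fam_of_tip[otu] <- fam
    } else {
      phy <- ape::bind.tree(phy, sub, where = tip_idx, position = 0)
      fam_of_tip[sub$tip.label] <- fam
    }
  }
  tips <- data.frame(label = phy$tip.label,
                     family = unname(fam_of_tip[phy$tip.label]),
                     stringsAsFactors = FALSE)
  tips$order <- if (!is.null(orders)) unname(orders[tips$family]) else NA_character_
  structure(list(phy = phy, tips = tips), class = "calibrated_tree")
}

#' Calibrate node ages by even interpolation between known ages (bladj)
#'
#' Fixed ages (root required; others optional) are honoured exactly; every
#' unconstrained internal node receives an age interpolated evenly, by node
#' count, along the path between its nearest constrained ancestor and its
#' nearest constrained descendant (tips sit at age 0). Branch lengths are
#' recomputed from the resulting ages, so the output is ultrametric.
#'
#' @param tree `calibrated_tree` or [ape::phylo] with node labels.
#' @param fixed_ages named numeric: names are node labels (or `"root"`),
#'   values are ages (time before present).
#' @return tree of the same class with recalibrated branch lengths.
#' @export
calibrate_ages <- function(tree, fixed_ages) {
  phy <- as_phylo(tree)
  phy <- ape::reorder.phylo(phy, "cladewise")
  n <- length(phy$tip.label); N <- phy$Nnode
  root <- n + 1L
  node_of <- function(nm) {
    if (nm == "root") return(root)
    if (is.null(phy$node.label)) {
      stop_classed("invalid_argument", "tree has no node labels to match '%s'", nm)
    }
    hit <- which(phy$node.label == nm)
    if (length(hit) != 1) {
      stop_classed("invalid_argument", "node label '%s' not found (or duplicated)", nm)
    }
    n + hit
  }
  age <- rep(NA_real_, n + N)
  age[seq_len(n)] <- 0
  fixed <- rep(FALSE, n + N)
  fixed[seq_len(n)] <- TRUE
  for (nm in names(fixed_ages)) {
    k <- node_of(nm)
    age[k] <- fixed_ages[[nm]]
    fixed[k] <- TRUE
  }
  if (is.na(age[root])) {
    stop_classed("invalid_argument", "root age must be fixed")
  }
  parent <- integer(n + N)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  children <- split(phy$edge[, 2], phy$edge[, 1])
  # consistency of the constraints: nearest fixed ancestor must be older
  for (k in which(fixed)) {
    a <- parent[k]
    while (a != 0 && !fixed[a]) a <- parent[a]
    if (a != 0 && age[a] < age[k] - 1e-12) {
      stop_classed("constraint_violation",
                   "fixed age of node %d (%.6g) exceeds its fixed ancestor %d (%.6g)",
                   k, age[k], a, age[a])
    }
  }
  # the constrained descendant reached through the longest chain of free
  # nodes below v: interpolating along that chain spreads the unconstrained
  # ages most evenly (a short side branch to a tip must not compress the
  # ages of a long uncalibrated backbone chain)
  longest_free_chain <- function(v) {
    best <- list(m = 0L, age = NA_real_)
    for (ch in children[[as.character(v)]]) {
      cand <- if (fixed[ch]) list(m = 0L, age = age[ch]) else {
        below <- longest_free_chain(ch)
        list(m = below$m + 1L, age = below$age)
      }
      if (cand$m > best$m || (cand$m == best$m &&
                              (is.na(best$age) || cand$age < best$age))) {
        best <- cand
      }
    }
    best
  }
  for (child in phy$edge[, 2]) {       # cladewise: parents are set first
    if (fixed[child] || child <= n) next
    if (!is.na(age[child])) next
    a_p <- age[parent[child]]
    d <- longest_free_chain(child)     # m free nodes strictly below child
    age[child] <- a_p - (a_p - d$age) / (d$m + 2L)
  }
  len <- age[phy$edge[, 1]] - age[phy$edge[, 2]]
  if (any(len < -1e-9)) {
    stop_classed("constraint_violation", "negative branch length after calibration")
  }
  phy$edge.length <- pmax(len, 0)
  if (inherits(tree, "calibrated_tree")) {
    tree$phy <- phy
    tree
  } else {
    phy
  }
}

#' Equalize terminal tip heights
#'
#' Extends each terminal branch so that all root-to-tip path lengths equal
#' the current maximum depth, giving the appearance of an ultrametric tree
#' with relative branch lengths; internal branches are untouched.
#'
#' @param tree `calibrated_tree` or [ape::phylo].
#' @return tree of the same class with equalized tip heights.
#' @export
equalize_tip_heights <- function(tree) {
  phy <- as_phylo(tree)
  n <- length(phy$tip.label)
  depths <- ape::node.depth.edgelength(phy)
  H <- max(depths[seq_len(n)])
  for (tip in seq_len(n)) {
    e <- which(phy$edge[, 2] == tip)
    newlen <- phy$edge.length[e] + (H - depths[tip])
    if (newlen < 0) {
      warning("negative terminal branch clamped to 0", call. = FALSE)
      newlen <- 0
    }
    phy$edge.length[e] <- newlen
  }
  if (inherits(tree, "calibrated_tree")) {
    tree$phy <- phy
    tree
  } else {
    phy
  }
}

#' Node ages of an ultrametric tree
#'
#' @param tree `calibrated_tree` or [ape::phylo] (ultrametric).
#' @return numeric vector of ages (time before present) indexed by node
#'   number (tips first).
#' @export
node_ages <- function(tree) {
  phy <- as_phylo(tree)
  depths <- ape::node.depth.edgelength(phy)
  max(depths) - depths
}

#' Ultrametricity check
#'
#' @param tree `calibrated_tree` or [ape::phylo].
#' @param tol absolute tolerance on root-to-tip path differences.
#' @return logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-8) {
  phy <- as_phylo(tree)
  d <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  diff(range(d)) <= tol
}
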