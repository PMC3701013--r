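#' Read a time-scaled phylogeny from Newick text
#'
#' Thin wrapper around [ape::read.tree()] that enforces the requirements of
#' time-calibrated comparative analyses: every branch must carry a length (in
#' Ma), lengths must be non-negative, and tip labels must be unique. Trees
#' need not be ultrametric; fossil tips simply end before the present.
#'
#' @param text a Newick string. Ignored when `file` is given.
#' @param file optional path to a Newick file.
#' @param default_brlen optional numeric; if supplied, branches with missing
#'   lengths are set to this value instead of raising an error. There is no
#'   silent default: time-calibrated analyses are branch-length sensitive.
#' @return an object of class `"phylo"`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(text = NULL, file = NULL, default_brlen = NULL) {
  if (is.null(text) && is.null(file)) stop("supply `text` or `file`")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)
  .check_newick_syntax(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse failed: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse failed: no tree found in string")
  if (is.null(tr$edge.length)) {
    if (is.null(default_brlen))
      stop("tree has no branch lengths; supply `default_brlen` to impute")
    tr$edge.length <- rep(default_brlen, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    if (is.null(default_brlen))
      stop("tree has branches with missing lengths; ",
           "supply `default_brlen` to impute")
    tr$edge.length[is.na(tr$edge.length)] <- default_brlen
  }
  validate_phylogeny(tr)
  tr
}

## Pre-parse structural scan so malformed input reports a character offset,
## which ape's parser does not.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character offset ", i)
    }
  }
  if (depth > 0L)
    stop("malformed Newick: ", depth, " unclosed '(' by character offset ",
         length(chars))
  if (!grepl(";\\s*$", text))
    stop("malformed Newick: missing terminal ';' at character offset ",
         length(chars))
  invisible(TRUE)
}

#' Serialise a phylogeny to Newick
#'
#' @param tree a `"phylo"` object.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

#' Validate the structural invariants of a time-scaled phylogeny
#'
#' Checks for a single root, non-negative branch lengths and unique tip
#' labels. Ultrametricity is deliberately not required (fossil tips).
#'
#' @param tree a `"phylo"` object.
#' @return `tree`, invisibly.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a \"phylo\" object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  ## exactly one root: one node that never appears as a child
  if (length(tree$tip.label) > 1L) {
    parents <- tree$edge[, 1]
    children <- tree$edge[, 2]
    roots <- setdiff(parents, children)
    if (length(roots) != 1L) stop("tree must have exactly one root")
  }
  invisible(tree)
}

#' Root-to-node path lengths
#'
#' @param tree a `"phylo"` object.
#' @return numeric vector of path lengths from the root, indexed by node
#'   number (tips first, then internal nodes).
#' @export
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Node ages before the present
#'
#' Ages are measured back from the deepest tip, i.e. the youngest tip is
#' taken to lie at the present (age 0). On a non-ultrametric tree fossil tips
#' get positive ages.
#'
#' @param tree a `"phylo"` object.
#' @return numeric vector of ages (Ma), indexed by node number.
#' @export
node_ages <- function(tree) {
  d <- node_depths(tree)
  max(d[seq_along(tree$tip.label)]) - d
}

#' Brownian-motion covariance structure of a phylogeny
#'
#' Entry (i, j) is the root-to-tip path length shared by tips i and j, i.e.
#' the depth of their most recent common ancestor; the diagonal holds total
#' root-to-tip path lengths. This is the expected trait covariance (up to the
#' rate) under Brownian motion.
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @return a symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_covariance <- function(tree) {
  validate_phylogeny(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (length(tree$tip.label) == 1L) {
    m <- matrix(sum(tree$edge.length), 1, 1,
                dimnames = list(tree$tip.label, tree$tip.label))
    return(m)
  }
  ape::vcv.phylo(tree)
}

#' Branch-length scaling parameters (Pagel's lambda, delta, kappa)
#'
#' @param lambda multiplier of phylogenetic covariance (internal branch
#'   lengths), in \[0, 1\].
#' @param delta exponent on node depths (overall path lengths), > 0.
#' @param kappa exponent on individual branch lengths, >= 0.
#' @return a list of class `"scaling_params"`.
#' @export
scaling_params <- function(lambda = 1, delta = 1, kappa = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("`lambda` must be a single number in [0, 1]")
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("`delta` must be a single positive number")
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa < 0)
    stop("`kappa` must be a single non-negative number")
  structure(list(lambda = lambda, delta = delta, kappa = kappa),
            class = "scaling_params")
}

#' Apply Pagel branch-length transforms to a covariance structure
#'
#' `lambda` multiplies all off-diagonal entries while leaving the diagonal
#' untouched (the covariance-matrix equivalent of multiplying internal branch
#' lengths); `delta` raises every entry, which is a shared path length, to
#' the power delta; `kappa` acts on individual branch lengths and therefore
#' requires the tree itself, from which the covariance is rebuilt after
#' raising each branch to the power kappa.
#'
#' @param cov covariance matrix from [phylo_covariance()].
#' @param params a [scaling_params()] object (or a lambda value).
#' @param tree the source tree; required only when `params$kappa != 1`.
#' @return the transformed covariance matrix.
#' @export
apply_scaling <- function(cov, params = scaling_params(), tree = NULL) {
  if (is.numeric(params)) params <- scaling_params(lambda = params)
  if (!inherits(params, "scaling_params"))
    stop("`params` must come from scaling_params()")
  if (params$kappa != 1) {
    if (is.null(tree))
      stop("kappa acts on branch lengths; supply `tree` to rebuild the ",
           "covariance from kappa-transformed branches")
    tk <- tree
    tk$edge.length <- tree$edge.length^params$kappa
    cov <- phylo_covariance(tk)
  }
  out <- cov
  if (params$lambda != 1) {
    d <- diag(out)
    out <- out * params$lambda
    diag(out) <- d
  }
  if (params$delta != 1) out <- out^params$delta
  out
}

## Covariance under scaling, straight from the tree.
scaled_covariance <- function(tree, params = scaling_params()) {
  apply_scaling(phylo_covariance(tree), params, tree = tree)
}

.node_id <- function(tree, label) {
  ntip <- length(tree$tip.label)
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(label, tree$node.label)
    if (!is.na(j)) return(ntip + j)
  }
  stop("attachment '", label, "' is neither a tip nor a node label")
}

## Attach a new tip at a given age on the edge subtending `node`.
.graft_at_age <- function(tree, taxon, node, attach_age, tip_age) {
  ages <- node_ages(tree)
  ntip <- length(tree$tip.label)
  if (node == ntip + 1L) stop("cannot graft above the root")
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  lo <- ages[node]; hi <- ages[parent]
  if (attach_age < lo - 1e-9 || attach_age > hi + 1e-9)
    stop(sprintf(
      "attachment age %.3f Ma outside the span [%.3f, %.3f] of the edge above '%s'",
      attach_age, lo, hi,
      if (node <= ntip) tree$tip.label[node] else paste0("node ", node)))
  if (tip_age > attach_age + 1e-9)
    stop("tip age must not exceed the attachment age")
  tiplet <- structure(list(
    edge = matrix(c(2L, 1L), 1, 2),
    tip.label = taxon,
    edge.length = attach_age - tip_age,
    Nnode = 1L), class = "phylo")
  out <- ape::bind.tree(tree, tiplet, where = node,
                        position = attach_age - lo)
  if (!is.null(out$node.label))
    out$node.label[is.na(out$node.label)] <- ""
  out
}

#' Graft a taxon (or a stem series of taxa) onto a time-scaled tree
#'
#' Inserts new tips on the edge above an existing tip or labelled internal
#' node, leaving all pre-existing pairwise path lengths untouched. Three
#' placement rules are supported: `"midpoint"` attaches at the temporal
#' midpoint of the edge; `"fixed_age"` attaches at a stated age;
#' `"ghost_minimized"` places successive extinct taxa along the stem at 1 Ma
#' intervals working down (i.e. back in time) from the crown node, the
#' convention that minimises implied ghost lineages. Under
#' `"ghost_minimized"` an older requested tip age pushes its attachment
#' deeper so branch lengths stay non-negative ("unless adjacent sister taxa
#' were geologically older").
#'
#' @param tree a `"phylo"` object.
#' @param taxon character vector of new tip labels (length > 1 only for
#'   `"ghost_minimized"`).
#' @param attachment label of the tip or internal node below the target edge.
#' @param rule one of `"midpoint"`, `"fixed_age"`, `"ghost_minimized"`.
#' @param age attachment age in Ma (for `"fixed_age"`).
#' @param tip_age age(s) at which the new tip(s) terminate; 0 = present.
#' @param interval spacing in Ma for `"ghost_minimized"` (default 1).
#' @return the augmented `"phylo"` object.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tr2 <- graft_taxon(tr, "X", "A", rule = "midpoint")
#' @export
graft_taxon <- function(tree, taxon, attachment,
                        rule = c("midpoint", "fixed_age", "ghost_minimized"),
                        age = NULL, tip_age = 0, interval = 1) {
  rule <- match.arg(rule)
  validate_phylogeny(tree)
  if (any(taxon %in% tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(intersect(taxon, tree$tip.label), collapse = ", "))
  if (anyDuplicated(taxon)) stop("duplicate labels within `taxon`")
  if (rule != "ghost_minimized" && length(taxon) != 1L)
    stop("grafting several taxa at once requires rule = \"ghost_minimized\"")
  tip_age <- rep_len(tip_age, length(taxon))

  if (rule == "midpoint") {
    node <- .node_id(tree, attachment)
    ages <- node_ages(tree)
    parent <- tree$edge[tree$edge[, 2] == node, 1]
    mid <- (ages[node] + ages[parent]) / 2
    return(.graft_at_age(tree, taxon, node, mid, tip_age))
  }
  if (rule == "fixed_age") {
    if (is.null(age)) stop("rule = \"fixed_age\" requires `age`")
    node <- .node_id(tree, attachment)
    return(.graft_at_age(tree, taxon, node, age, tip_age))
  }
  ## ghost_minimized: successive 1-Ma steps below the crown node `attachment`.
  ## Ages are laid out first (oldest pushed deeper if a tip is geologically
  ## older than its slot), then grafts run deepest-first so every insertion
  ## lands on the edge directly above `attachment`.
  node <- .node_id(tree, attachment)
  crown_age <- node_ages(tree)[node]
  attach_age <- numeric(length(taxon))
  prev <- crown_age
  for (k in seq_along(taxon)) {
    prev <- max(prev + interval, tip_age[k])
    attach_age[k] <- prev
  }
  out <- tree
  for (k in rev(seq_along(taxon))) {
    nd <- .node_id(out, attachment)
    out <- .graft_at_age(out, taxon[k], nd, attach_age[k], tip_age[k])
  }
  out
}

#' Pairwise root-to-tip distance matrix between tips
#'
#' Patristic distances, used by the round-trip and grafting invariance
#' checks.
#'
#' @param tree a `"phylo"` object.
#' @return symmetric matrix of patristic distances.
#' @export
tip_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}
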