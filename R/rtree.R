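# Rooted-tree data model.
#
# A tree is stored as parallel parent/children tables over integer vertex ids
# 1..nv. Every tree carries a *superroot*: an auxiliary vertex above the root
# whose single outgoing edge is the *root edge* (root tube for species trees).
# Edges are identified by their lower terminus, so the tube set of a species
# tree is exactly its non-superroot vertex set and the root tube is identified
# by the root itself.

#' Construct a rooted tree from a parent table
#'
#' Low-level constructor used by the parsers, the simulator and the tree
#' surgery operations. Vertices are integers `1..length(parent)`; the
#' superroot is the unique vertex with `NA` parent.
#'
#' @param parent integer vector; `parent[v]` is the parent of vertex `v`,
#'   `NA` for the superroot.
#' @param label character vector; leaf labels (`NA` for internal vertices).
#'   For gene trees a label of the form `id@species` assigns the leaf to
#'   `species` (the substring after the last `@`); a bare label is its own
#'   species.
#' @param role `"gene"` or `"species"`.
#' @param subdiv logical vector flagging inserted single-child (subdivision)
#'   vertices; such vertices are the only non-superroot vertices allowed to
#'   have exactly one child.
#' @param outgroup logical vector flagging auxiliary outgroup-chain vertices.
#' @param validate check structural invariants (default `TRUE`).
#' @return An object of class `rtree`.
#' @export
rtree_build <- function(parent, label = rep(NA_character_, length(parent)),
                        role = c("gene", "species"),
                        subdiv = rep(FALSE, length(parent)),
                        outgroup = rep(FALSE, length(parent)),
                        validate = TRUE) {
  role <- match.arg(role)
  nv <- length(parent)
  parent <- as.integer(parent)
  children <- vector("list", nv)
  for (v in seq_len(nv)) children[[v]] <- integer(0)
  for (v in seq_len(nv)) {
    p <- parent[v]
    if (!is.na(p)) children[[p]] <- c(children[[p]], v)
  }
  sr <- which(is.na(parent))
  t <- structure(list(
    nv = nv, parent = parent, children = children,
    label = as.character(label), species = species_part(as.character(label)),
    superroot = if (length(sr) == 1L) sr else NA_integer_,
    root = if (length(sr) == 1L && length(children[[sr]]) >= 1L)
      children[[sr]][1L] else NA_integer_,
    subdiv = subdiv, outgroup = outgroup, role = role
  ), class = "rtree")
  if (validate) rt_validate(t)
  t
}

#' Species part of a gene leaf label
#'
#' The species name is the substring after the last `@`; a label without `@`
#' is its own species name.
#'
#' @param label character vector of leaf labels.
#' @return character vector of species names (`NA` where `label` is `NA`).
#' @export
species_part <- function(label) {
  vapply(label, function(x) {
    if (is.na(x)) return(NA_character_)
    at <- gregexpr("@", x, fixed = TRUE)[[1]]
    if (at[1] == -1L) x else substring(x, max(at) + 1L)
  }, character(1), USE.NAMES = FALSE)
}

rt_validate <- function(t) {
  nv <- t$nv
  if (is.na(t$superroot)) stop("tree must have exactly one superroot (NA parent)")
  if (length(t$children[[t$superroot]]) < 1L) stop("superroot must have a child")
  if (length(t$children[[t$superroot]]) > 2L)
    stop("superroot may have at most two children (root plus outgroup chain)")
  if (length(t$children[[t$superroot]]) == 2L &&
      !t$outgroup[t$children[[t$superroot]][2L]])
    stop("second superroot child must be an outgroup chain")
  # acyclicity + reachability
  seen <- logical(nv)
  stack <- t$superroot
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[v]) stop("cycle detected in parent table")
    seen[v] <- TRUE
    stack <- c(stack, t$children[[v]])
  }
  if (!all(seen)) stop("tree has vertices unreachable from the superroot")
  deg <- lengths(t$children)
  bad <- which(deg == 1L & seq_len(nv) != t$superroot & !t$subdiv & !t$outgroup)
  if (length(bad))
    stop("internal vertex with exactly one child (not superroot/subdivision): ",
         bad[1])
  leaves <- which(deg == 0L)
  if (any(is.na(t$label[leaves]) & !t$outgroup[leaves]))
    stop("every leaf must carry a label")
  if (t$role == "species") {
    labs <- t$label[leaves]
    labs <- labs[!is.na(labs)]
    if (anyDuplicated(labs))
      stop("duplicate species leaf label: ", labs[duplicated(labs)][1])
  }
  invisible(t)
}

#' @export
print.rtree <- function(x, ...) {
  cat(sprintf("<rtree role=%s, %d vertices, %d leaves> %s\n",
              x$role, x$nv, length(rt_leaves(x)), write_newick(x)))
  invisible(x)
}

#' Leaf vertices of a tree
#' @param t an `rtree`.
#' @return integer vector of leaf vertex ids.
#' @export
rt_leaves <- function(t) which(lengths(t$children) == 0L)

#' Vertices in postorder (children before parents, superroot last)
#' @param t an `rtree`.
#' @return integer vector of all vertex ids.
#' @export
rt_postorder <- function(t) {
  out <- integer(0)
  rec <- function(v) {
    for (c in t$children[[v]]) rec(c)
    out[[length(out) + 1L]] <<- v
  }
  rec(t$superroot)
  unlist(out)
}

#' Ancestors of a vertex, from its parent up to the superroot
#' @param t an `rtree`.
#' @param v vertex id.
#' @return integer vector (possibly empty for the superroot).
#' @export
rt_ancestors <- function(t, v) {
  out <- integer(0)
  p <- t$parent[v]
  while (!is.na(p)) { out <- c(out, p); p <- t$parent[p] }
  out
}

#' Natural order test: is `u` weakly below `v`?
#'
#' `u` is weakly below `v` when `v` lies on the path from `u` to the
#' superroot (including `u == v`).
#'
#' @param t an `rtree`.
#' @param u,v vertex ids.
#' @return logical.
#' @export
rt_weakly_below <- function(t, u, v) {
  if (u == v) return(TRUE)
  p <- t$parent[u]
  while (!is.na(p)) { if (p == v) return(TRUE); p <- t$parent[p] }
  FALSE
}

# Position helpers: a *position* in a species tree is either a vertex v or the
# tube above v (identified by its lower vertex v). pos (v1,tube1) weakly below
# (v2,tube2) in the natural order on the union of vertices and tubes.
pos_weakly_below <- function(t, v1, tube1, v2, tube2) {
  if (v1 == v2) return(tube1 == tube2 || (!tube1 && tube2))
  rt_weakly_below(t, v1, v2)
}

pos_strictly_below <- function(t, v1, tube1, v2, tube2) {
  pos_weakly_below(t, v1, tube1, v2, tube2) && !(v1 == v2 && tube1 == tube2)
}

#' Clade of a vertex
#'
#' The set (not multiset) of species names present at the leaves weakly below
#' `v`. For a gene tree the species parts of the leaf labels are used, so the
#' clade of a cherry of in-paralogs `(x@a, y@a)` is the singleton `{a}`.
#'
#' @param tree an `rtree`.
#' @param v vertex id.
#' @return sorted character vector of species names.
#' @export
clade_of <- function(tree, v) {
  if (v < 1L || v > tree$nv) stop("unknown vertex: ", v)
  below <- rt_descendant_leaves(tree, v)
  sort(unique(tree$species[below]))
}

rt_descendant_leaves <- function(t, v) {
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    ch <- t$children[[x]]
    if (!length(ch)) out <- c(out, x) else stack <- c(stack, ch)
  }
  out[!t$outgroup[out]]
}

#' Last common ancestor of a set of species names
#'
#' The unique minimal vertex whose clade contains all of `labels`.
#'
#' @param tree an `rtree`, usually a species tree.
#' @param labels nonempty character vector of species names.
#' @return a vertex id.
#' @export
lca_of <- function(tree, labels) {
  labels <- unique(labels)
  if (!length(labels)) stop("labels must be nonempty")
  leafv <- rt_leaves(tree)
  hit <- match(labels, tree$species[leafv])
  if (anyNA(hit)) stop("label absent from tree: ", labels[which(is.na(hit))[1]])
  vs <- leafv[hit]
  cur <- vs[1]
  for (v in vs[-1]) {
    # walk cur upward until it is an ancestor of v
    while (!rt_weakly_below(tree, v, cur)) cur <- tree$parent[cur]
  }
  cur
}

#' Prune a tree to a set of species
#'
#' Removes every maximal subtree whose clade is disjoint from `keep`, then
#' merges each resulting single-child chain into one edge. The clade of the
#' result equals the tree's clade intersected with `keep`.
#'
#' @param tree an `rtree`.
#' @param keep character vector of species names to retain.
#' @return an `rtree` of the same role.
#' @export
prune_to <- function(tree, keep) {
  leafv <- rt_leaves(tree)
  keep_leaf <- leafv[tree$species[leafv] %in% keep]
  if (!length(keep_leaf))
    stop("prune_to: no species of the tree is in 'keep'")
  # vertices kept: ancestors of kept leaves
  keepv <- logical(tree$nv)
  for (v in keep_leaf) { keepv[v] <- TRUE; keepv[rt_ancestors(tree, v)] <- TRUE }
  # rebuild, suppressing unary vertices (except superroot)
  old2new <- integer(tree$nv)
  np <- integer(0); nl <- character(0); nsub <- logical(0)
  add <- function(parent_new, lab, sub) {
    np[[length(np) + 1L]] <<- parent_new
    nl[[length(nl) + 1L]] <<- lab
    nsub[[length(nsub) + 1L]] <<- sub
    length(np)
  }
  rec <- function(v, parent_new) {
    ch <- t_children_kept(tree, v, keepv)
    while (length(ch) == 1L && v != tree$superroot) {
      v <- ch
      ch <- t_children_kept(tree, v, keepv)
    }
    id <- add(parent_new, tree$label[v], FALSE)
    for (c in ch) rec(c, id)
    id
  }
  rec(tree$superroot, NA_integer_)
  rtree_build(unlist(np), unlist(nl), role = tree$role, subdiv = unlist(nsub))
}

t_children_kept <- function(t, v, keepv) {
  ch <- t$children[[v]]
  ch[keepv[ch]]
}

# ---- Newick I/O (via ape) ---------------------------------------------------

#' Parse a rooted Newick string
#'
#' Parsing is delegated to [ape::read.tree()]; a superroot and root edge are
#' added above the Newick root. Branch lengths are parsed and ignored. Gene
#' leaf labels of the form `id@species` are assigned to the species named
#' after the last `@`.
#'
#' @param text a Newick string (one tree).
#' @param role `"gene"` or `"species"`; species trees must have unique leaf
#'   labels.
#' @return an `rtree`.
#' @export
parse_newick <- function(text, role = c("gene", "species")) {
  role <- match.arg(role)
  text <- trimws(text)
  newick_check(text)
  body <- sub(";\\s*$", "", text)
  if (!grepl("[(),]", body)) {
    # single-leaf tree: superroot -> leaf
    lab <- sub(":[^:]*$", "", body)
    return(rtree_build(c(NA_integer_, 1L), c(NA_character_, lab), role = role))
  }
  ph <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(ph)) stop("malformed Newick near position 1: unparseable tree")
  ntip <- length(ph$tip.label)
  nv <- ntip + ph$Nnode
  parent <- rep(NA_integer_, nv + 1L)
  parent[ph$edge[, 2]] <- ph$edge[, 1]
  sr <- nv + 1L
  rootv <- ntip + 1L
  parent[rootv] <- sr
  label <- c(ph$tip.label, rep(NA_character_, ph$Nnode + 1L))
  t <- rtree_build(parent, label, role = role, validate = FALSE)
  # keep children in Newick input order (cladewise edge order)
  for (p in unique(ph$edge[, 1]))
    t$children[[p]] <- ph$edge[ph$edge[, 1] == p, 2]
  t <- rt_suppress_unary(t)
  rt_validate(t)
  t
}

# cheap well-formedness check with a character position in the message
newick_check <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick near position ", i, ": unbalanced ')'")
    }
  }
  if (depth != 0L)
    stop("malformed Newick near position ", length(chars),
         ": ", depth, " unclosed '('")
  if (!grepl(";\\s*$", text))
    stop("malformed Newick near position ", max(1L, length(chars)),
         ": missing terminal ';'")
  invisible(TRUE)
}

# collapse non-superroot single-child vertices (merging their edges)
rt_suppress_unary <- function(t) {
  np <- integer(0); nl <- character(0)
  add <- function(parent_new, lab) {
    np[[length(np) + 1L]] <<- parent_new
    nl[[length(nl) + 1L]] <<- lab
    length(np)
  }
  rec <- function(v, parent_new) {
    ch <- t$children[[v]]
    while (length(ch) == 1L && v != t$superroot) {
      v <- ch
      ch <- t$children[[v]]
    }
    id <- add(parent_new, t$label[v])
    for (c in ch) rec(c, id)
    id
  }
  rec(t$superroot, NA_integer_)
  rtree_build(unlist(np), unlist(nl), role = t$role)
}

#' Write a tree as a Newick string
#'
#' The superroot, subdivision vertices and any outgroup chain are suppressed
#' on output; the result round-trips through [parse_newick()].
#'
#' @param tree an `rtree`.
#' @return a Newick string ending in `";"`.
#' @export
write_newick <- function(tree) {
  t <- tree
  if (any(t$outgroup)) t <- rt_drop_outgroup(t)
  if (any(t$subdiv)) t <- rt_suppress_unary(t)
  leaves <- rt_leaves(t)
  if (length(leaves) == 1L) return(paste0(t$label[leaves], ";"))
  ph <- rt_to_phylo(t)
  ape::write.tree(ph)
}

rt_drop_outgroup <- function(t) {
  keepv <- !t$outgroup
  np <- integer(0); nl <- character(0); nsub <- logical(0)
  add <- function(parent_new, lab, sub) {
    np[[length(np) + 1L]] <<- parent_new
    nl[[length(nl) + 1L]] <<- lab
    nsub[[length(nsub) + 1L]] <<- sub
    length(np)
  }
  rec <- function(v, parent_new) {
    id <- add(parent_new, t$label[v], t$subdiv[v])
    for (c in t$children[[v]]) if (keepv[c]) rec(c, id)
    id
  }
  rec(t$superroot, NA_integer_)
  rtree_build(unlist(np), unlist(nl), role = t$role, subdiv = unlist(nsub))
}

rt_to_phylo <- function(t) {
  leaves <- rt_leaves(t)
  ntip <- length(leaves)
  internals <- setdiff(which(lengths(t$children) > 0L), t$superroot)
  ids <- integer(t$nv)
  ids[leaves] <- seq_len(ntip)
  # root first among internals (ape convention)
  internals <- c(t$root, setdiff(internals, t$root))
  ids[internals] <- ntip + seq_along(internals)
  edge <- matrix(0L, nrow = t$nv - 2L, ncol = 2L)  # all edges except root edge
  k <- 0L
  emit <- function(v) {                    # preorder: cladewise edge order
    for (c in t$children[[v]]) {
      k <<- k + 1L
      edge[k, ] <<- c(ids[v], ids[c])
      emit(c)
    }
  }
  emit(t$root)
  structure(list(edge = edge[seq_len(k), , drop = FALSE],
                 tip.label = t$label[leaves],
                 Nnode = length(internals)),
            class = "phylo", order = "cladewise")
}

#' Number of leaves of a tree
#' @param t an `rtree`.
#' @return integer.
#' @export
rt_n_leaves <- function(t) length(rt_leaves(t))

#' All species names present in a tree
#' @param t an `rtree`.
#' @return sorted character vector.
#' @export
rt_species_set <- function(t) {
  leaves <- rt_leaves(t)
  sort(unique(t$species[leaves[!t$outgroup[leaves]]]))
}

#' Is the tree binary?
#'
#' Subdivision and outgroup vertices are ignored; every other internal vertex
#' must have exactly two children.
#'
#' @param t an `rtree`.
#' @return logical.
#' @export
rt_is_binary <- function(t) {
  deg <- lengths(t$children)
  int <- which(deg > 0L & seq_len(t$nv) != t$superroot & !t$subdiv & !t$outgroup)
  all(deg[int] == 2L)
}
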