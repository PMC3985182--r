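# Binarization of polytomous gene trees against a binary species tree.
#
# d(g) denotes the tube entering LCA(g) in S (equivalently the canonical
# image of g when that image is a tube). An edge e of G *enters* a tube d
# when d(e+) for the upper terminus lies strictly above d and d lies weakly
# above d(e-) for the lower terminus; the superroot's image is treated as
# strictly above every tube. A *bundle* for d is a maximal set of entering
# edges sharing their upper terminus. The paralogous binarization G## of G
# against S resolves every polytomy so that each tube receives the minimal
# possible number of entering edges, namely the bundle count p(G, d); all
# paralogous binarizations have equal reconciliation cost.

# per-vertex tube d(g): the species vertex identifying the tube entering
# LCA(clade(g)); the superroot gets NA (conceptually above everything).
d_of_map <- function(G, S) {
  cl <- g_clades(G)
  leafv <- rt_leaves(S)
  leafmap <- stats::setNames(leafv, S$species[leafv])
  dof <- integer(G$nv)
  for (g in seq_len(G$nv)) {
    if (g == G$superroot) { dof[g] <- NA_integer_; next }
    dof[g] <- lca_of(S, cl[[g]])
  }
  dof
}

#' Does a gene edge enter a species tube?
#'
#' True when the tube of the edge's upper terminus lies strictly above `d`
#' and `d` lies weakly above the tube of the lower terminus (the superroot's
#' tube counts as strictly above every tube of `S`).
#'
#' @param G,S gene and binary species `rtree`s.
#' @param e a gene edge, identified by its lower vertex.
#' @param d a species tube, identified by its lower vertex.
#' @return logical.
#' @export
enters_tube <- function(G, S, e, d) {
  dof <- d_of_map(G, S)
  enters_tube_impl(G, S, e, d, dof)
}

enters_tube_impl <- function(G, S, e, d, dof) {
  p <- G$parent[e]
  up <- dof[p]
  # d(e+) strictly above d
  above <- if (is.na(up)) TRUE else (up != d && rt_weakly_below(S, d, up))
  if (!above) return(FALSE)
  rt_weakly_below(S, dof[e], d)              # d weakly above d(e-)
}

#' Bundles of entering edges for a tube
#'
#' Partitions the edges of `G` entering `d` by their upper terminus; the
#' number of bundles `p(G, d)` is the minimal number of edges any candidate
#' binarization of `G` can send into `d`.
#'
#' @inheritParams enters_tube
#' @return list of bundles, each a list with `parent_vertex` and `edges`
#'   (lower vertices of the member edges), ordered by parent vertex.
#' @export
bundles_for <- function(G, S, d) {
  dof <- d_of_map(G, S)
  ent <- Filter(function(e) enters_tube_impl(G, S, e, d, dof),
                setdiff(seq_len(G$nv), G$superroot))
  if (!length(ent)) return(list())
  par <- G$parent[ent]
  out <- lapply(sort(unique(par)), function(p)
    list(parent_vertex = p, edges = sort(ent[par == p])))
  out
}

#' One binarization step at a polytomous vertex
#'
#' Splits the children of `g` into the two parts `A` and `B`, introducing an
#' intercalating vertex above each non-singleton part, so `g` becomes binary;
#' clades of all pre-existing vertices are preserved.
#'
#' @param Gp a gene `rtree`.
#' @param g a polytomous vertex of `Gp`.
#' @param A,B disjoint nonempty sets of children of `g` covering all of them.
#' @return a gene `rtree`.
#' @export
binarization_step <- function(Gp, g, A, B) {
  ch <- Gp$children[[g]]
  if (length(ch) <= 2L) stop("vertex ", g, " is not polytomous")
  A <- as.integer(A); B <- as.integer(B)
  if (!length(A) || !length(B) || length(intersect(A, B)) ||
      !setequal(c(A, B), ch))
    stop("A and B must partition the children of vertex ", g)
  np <- integer(0); nl <- character(0)
  add <- function(parent_new, lab) {
    np[[length(np) + 1L]] <<- parent_new
    nl[[length(nl) + 1L]] <<- lab
    length(np)
  }
  copy <- function(v, parent_new) {
    id <- add(parent_new, Gp$label[v])
    if (v == g) {
      pa <- if (length(A) == 1L) id else add(id, NA_character_)
      for (c in A) copy(c, pa)
      pb <- if (length(B) == 1L) id else add(id, NA_character_)
      for (c in B) copy(c, pb)
    } else {
      for (c in Gp$children[[v]]) copy(c, id)
    }
    id
  }
  copy(Gp$superroot, NA_integer_)
  rtree_build(unlist(np), unlist(nl), role = Gp$role)
}

#' Paralogous binarization of a gene tree against a species tree
#'
#' Resolves every polytomy by the three-part rule: children g' with
#' `d(g') = d(g)` form the first part, children below the two child tubes of
#' `d(g)` the second and third. When only the first part is nonempty it is
#' split deterministically (first child vs. the rest); when the first part
#' and at least one other are nonempty, the split is first part vs. union of
#' the others; otherwise second vs. third part. The result G## sends the
#' minimal number `p(G, d)` of entering edges into every tube, and all
#' paralogous binarizations of (G, S) have equal reconciliation cost.
#'
#' @param G a (possibly polytomous) gene `rtree`.
#' @param S a binary species `rtree`.
#' @return a binary gene `rtree`.
#' @export
paralogous_binarization <- function(G, S) {
  if (!rt_is_binary(S)) stop("species tree must be binary")
  repeat {
    poly <- which(lengths(G$children) > 2L)
    if (!length(poly)) return(G)
    g <- poly[1]
    dof <- d_of_map(G, S)
    dg <- dof[g]
    ch <- G$children[[g]]
    sch <- S$children[[dg]]
    part1 <- ch[dof[ch] == dg]
    if (length(sch) == 2L) {
      part2 <- ch[vapply(ch, function(c) rt_weakly_below(S, dof[c], sch[1]),
                         logical(1))]
      part3 <- ch[vapply(ch, function(c) rt_weakly_below(S, dof[c], sch[2]),
                         logical(1))]
    } else {
      part2 <- integer(0); part3 <- integer(0)
    }
    if (length(part1) && !length(part2) && !length(part3)) {
      A <- part1[1]; B <- part1[-1]
    } else if (length(part1)) {
      A <- part1; B <- c(part2, part3)
    } else {
      A <- part2; B <- part3
    }
    G <- binarization_step(G, g, A, B)
  }
}

#' Duplications forced in a leaf tube by a polytomous gene tree
#'
#' `Par'(G, s) = L - p(G, d)` where `d` is the leaf tube of species `s`, `L`
#' the total number of leaves below the edges of the bundles for `d`, and
#' `p(G, d)` the bundle count; equals the number of duplications the
#' canonical mapping of any paralogous binarization locates in that leaf
#' tube. On binary gene trees it coincides with [par_count()].
#'
#' @param G a gene `rtree`.
#' @param S a binary species `rtree`.
#' @param s a species name, a leaf of `S`.
#' @return integer.
#' @export
par_prime <- function(G, S, s) {
  leafv <- rt_leaves(S)
  d <- leafv[match(s, S$species[leafv])]
  if (is.na(d)) stop("unknown species: ", s)
  bs <- bundles_for(G, S, d)
  if (!length(bs)) return(0L)
  L <- sum(vapply(bs, function(b)
    sum(vapply(b$edges, function(e) length(rt_descendant_leaves(G, e)),
               integer(1))), integer(1)))
  L - length(bs)
}

#' Event census for a partition on polytomous gene trees (Phase-1 variant)
#'
#' Computes the bundle counts for the conceptual tubes of the join of
#' `S(V1)` and `S(V2)`: `n` (bundles for the joined root tube), `n1`, `n2`
#' (bundles for the halves' root tubes), and `k` (bundle pairs for the two
#' halves sharing a parent vertex), plus the restrictions to gene trees
#' whose root clade meets both halves (primed, explicit losses) or exactly
#' one (double primed, implicit losses). Entering is decided cladewise, so
#' no binarization is materialized. On binary input the derived event counts
#' reproduce [q_counts()] exactly: `q1 = k`, `q2 = n1 + n2 - n - k`,
#' `q3' = n1' + n2' - 2k'`, `q3'' = n1'' + n2'' - 2k''`.
#'
#' @param Gjs list of gene `rtree`s (possibly polytomous).
#' @param V1,V2 disjoint nonempty species-name sets.
#' @return named numeric vector with elements `n, n1, n2, k, n1p, n2p, kp,
#'   n1pp, n2pp, kpp`.
#' @export
poly_q_counts <- function(Gjs, V1, V2) {
  V1 <- sort(unique(V1)); V2 <- sort(unique(V2))
  if (length(intersect(V1, V2))) stop("V1 and V2 must be disjoint")
  if (!length(V1) || !length(V2)) stop("V1 and V2 must be nonempty")
  V <- c(V1, V2)
  tot <- c(n = 0L, n1 = 0L, n2 = 0L, k = 0L, n1p = 0L, n2p = 0L, kp = 0L,
           n1pp = 0L, n2pp = 0L, kpp = 0L)
  for (G in Gjs) {
    cl <- g_clades(G)
    rootcl <- cl[[G$root]]
    meets1 <- length(intersect(rootcl, V1)) > 0L
    meets2 <- length(intersect(rootcl, V2)) > 0L
    cond_i <- meets1 && meets2
    cond_ii <- xor(meets1, meets2)
    # entering conditions, cladewise: e enters the root tube of the tree over
    # W iff clade(e-) is inside W and clade(e+) is not (superroot: always not)
    enters <- function(e, W) {
      if (!all(cl[[e]] %in% W)) return(FALSE)
      p <- G$parent[e]
      p == G$superroot || !all(cl[[p]] %in% W)
    }
    edges <- setdiff(seq_len(G$nv), G$superroot)
    e_n  <- Filter(function(e) enters(e, V), edges)
    e_n1 <- Filter(function(e) enters(e, V1), edges)
    e_n2 <- Filter(function(e) enters(e, V2), edges)
    n  <- length(unique(G$parent[e_n]))
    n1 <- length(unique(G$parent[e_n1]))
    n2 <- length(unique(G$parent[e_n2]))
    k  <- length(intersect(unique(G$parent[e_n1]), unique(G$parent[e_n2])))
    tot["n"] <- tot["n"] + n
    tot["n1"] <- tot["n1"] + n1; tot["n2"] <- tot["n2"] + n2
    tot["k"] <- tot["k"] + k
    if (cond_i) {
      tot["n1p"] <- tot["n1p"] + n1; tot["n2p"] <- tot["n2p"] + n2
      tot["kp"] <- tot["kp"] + k
    }
    if (cond_ii) {
      tot["n1pp"] <- tot["n1pp"] + n1; tot["n2pp"] <- tot["n2pp"] + n2
      tot["kpp"] <- tot["kpp"] + k
    }
  }
  tot
}

# Eq-12 style census adapter: returns the (q1, q2, q3', q3'') event counts of
# the polytomous recursion so phase1() can consume it unchanged.
poly_q_as_q <- function(Gjs, V1, V2) {
  p <- poly_q_counts(Gjs, V1, V2)
  c(q1 = unname(p["k"]),
    q2 = unname(p["n1"] + p["n2"] - p["n"] - p["k"]),
    q3p = unname(p["n1p"] + p["n2p"] - 2 * p["kp"]),
    q3pp = unname(p["n1pp"] + p["n2pp"] - 2 * p["kpp"]))
}

#' Phase 1 for polytomous gene trees
#'
#' Identical control flow to [phase1()], with the join-cost census replaced
#' by the bundle-based counts of [poly_q_counts()] and the singleton base
#' using [par_prime()] (duplications forced by any paralogous binarization).
#' The resulting table feeds [phase2()] unchanged and minimizes the total
#' reconciliation cost of the paralogous binarizations of the inputs.
#'
#' @inheritParams phase1
#' @return a `basic_table`.
#' @export
phase1_polytomous <- function(Gjs, P = default_clade_family(Gjs),
                              costs = event_costs()) {
  if (inherits(Gjs, "rtree")) Gjs <- list(Gjs)
  phase1(Gjs, P, costs, q_fun = poly_q_as_q, singleton_par = par_prime_cladewise)
}

# Par'(G, s) without a host species tree: an edge enters the leaf tube of s
# iff the clade of its lower terminus is {s} and its upper terminus is the
# superroot or has a larger clade; by the locality lemmas this agrees with
# par_prime() against any host containing s.
par_prime_cladewise <- function(G, s) {
  cl <- g_clades(G)
  edges <- setdiff(seq_len(G$nv), G$superroot)
  ent <- Filter(function(e) {
    if (!identical(cl[[e]], s)) return(FALSE)
    p <- G$parent[e]
    p == G$superroot || !identical(cl[[p]], s)
  }, edges)
  if (!length(ent)) return(0L)
  L <- sum(vapply(ent, function(e) length(rt_descendant_leaves(G, e)), integer(1)))
  L - length(unique(G$parent[ent]))
}
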