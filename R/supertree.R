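# Two-phase conditional supertree construction from many gene trees.
#
# The conditional problem constrains the species tree's clades to a
# predefined clade family P (which must contain every clade of every input
# gene tree). Phase 1 is an exact dynamic program over the *basic* members of
# P: a singleton is basic; a larger set V is basic when it splits into two
# disjoint basic members of P covering V. For every basic V a minimal-cost
# *basic tree* S(V) is built bottom-up by joining the best partition's two
# basic trees under a new root; the added cost of the join counts exactly the
# events localized at the new root vertex r and root tube d of the merged
# tree, via the census q1 (divergences at r), q2 (duplications in d), q3'
# (explicit losses at r), q3'' (implicit losses at r) over all gene trees.
# When the full species set V0 is basic, S(V0) is the conditional global
# optimum. Phase 2 is a reliability-weighted augmentation heuristic that
# assembles basic trees into a full species tree when V0 is not basic (or as
# a robustness device): starting from the best-supported 3-species tree it
# adds one species at a time at the cheapest insertion edge, scoring
# candidates by c * (2 - R) with reliability R = (c' - c)/c' computed from
# the best (c) and second-best (c') candidate costs.

set_key <- function(v) paste(sort(unique(v)), collapse = "\r")
key_set <- function(k) strsplit(k, "\r", fixed = TRUE)[[1]]

#' Clade family for the conditional supertree problem
#'
#' @param universe character vector of all species names (V0).
#' @param members list of character vectors, the permitted clades.
#' @return An object of class `clade_family` (deduplicated, sorted by
#'   cardinality then lexicographically).
#' @export
clade_family <- function(universe, members) {
  universe <- sort(unique(universe))
  members <- lapply(members, function(m) sort(unique(m)))
  if (any(vapply(members, length, integer(1)) == 0L))
    stop("clade family members must be nonempty")
  bad <- unlist(members)[!unlist(members) %in% universe]
  if (length(bad)) stop("clade family member outside the universe: ", bad[1])
  keys <- vapply(members, set_key, character(1))
  members <- members[!duplicated(keys)]
  ord <- order(vapply(members, length, integer(1)),
               vapply(members, set_key, character(1)))
  structure(list(universe = universe, members = members[ord]),
            class = "clade_family")
}

#' Default clade family: gene-tree clades, singletons, and V0
#'
#' @param Gjs list of gene `rtree`s.
#' @return a `clade_family`.
#' @export
default_clade_family <- function(Gjs) {
  V0 <- sort(unique(unlist(lapply(Gjs, rt_species_set))))
  members <- list()
  for (G in Gjs)
    for (v in setdiff(seq_len(G$nv), G$superroot))
      members[[length(members) + 1L]] <- clade_of(G, v)
  for (s in V0) members[[length(members) + 1L]] <- s
  members[[length(members) + 1L]] <- V0
  clade_family(V0, members)
}

#' Event census for a candidate partition
#'
#' For the partition of `V = union(V1, V2)` into `V1` and `V2`, counts over
#' all gene trees: `q1` vertices whose two child clades fall into the two
#' halves (divergences at the join root), `q2` non-superroot vertices whose
#' clade lies in `V` with a child clade meeting both halves (duplications in
#' the join's root tube), and edges inducing losses at the join root —
#' `q3p` in trees whose root clade meets both halves (explicit) and `q3pp`
#' in trees whose root clade meets exactly one (implicit).
#'
#' @param Gjs list of gene `rtree`s.
#' @param V1,V2 disjoint nonempty species-name sets.
#' @return named numeric vector `c(q1, q2, q3p, q3pp)`.
#' @export
q_counts <- function(Gjs, V1, V2) {
  V1 <- sort(unique(V1)); V2 <- sort(unique(V2))
  if (length(intersect(V1, V2))) stop("V1 and V2 must be disjoint")
  if (!length(V1) || !length(V2)) stop("V1 and V2 must be nonempty")
  V <- c(V1, V2)
  q1 <- q2 <- q3p <- q3pp <- 0L
  for (G in Gjs) {
    cl <- g_clades(G)
    rootcl <- cl[[G$root]]
    meets1 <- length(intersect(rootcl, V1)) > 0L
    meets2 <- length(intersect(rootcl, V2)) > 0L
    cond_i <- meets1 && meets2
    cond_ii <- xor(meets1, meets2)
    for (g in seq_len(G$nv)) {
      ch <- G$children[[g]]
      if (!length(ch)) next
      if (g != G$superroot && length(ch) == 2L) {
        c1 <- cl[[ch[1]]]; c2 <- cl[[ch[2]]]
        if ((all(c1 %in% V1) && all(c2 %in% V2)) ||
            (all(c1 %in% V2) && all(c2 %in% V1))) q1 <- q1 + 1L
      }
      if (g != G$superroot && all(cl[[g]] %in% V)) {
        straddle <- vapply(ch, function(c)
          length(intersect(cl[[c]], V1)) > 0L && length(intersect(cl[[c]], V2)) > 0L,
          logical(1))
        if (any(straddle)) q2 <- q2 + 1L
      }
    }
    if (cond_i || cond_ii) {
      for (e in setdiff(seq_len(G$nv), G$superroot)) {
        ce <- cl[[e]]
        if (!(all(ce %in% V1) || all(ce %in% V2))) next
        p <- G$parent[e]
        ok <- if (p == G$superroot) TRUE else {
          sib <- setdiff(G$children[[p]], e)
          all(vapply(sib, function(g)
            !all(cl[[g]] %in% V1) && !all(cl[[g]] %in% V2), logical(1)))
        }
        if (ok) {
          if (cond_i) q3p <- q3p + 1L else q3pp <- q3pp + 1L
        }
      }
    }
  }
  c(q1 = q1, q2 = q2, q3p = q3p, q3pp = q3pp)
}

g_clades <- function(G) {
  cl <- vector("list", G$nv)
  for (v in rt_postorder(G)) {
    ch <- G$children[[v]]
    cl[[v]] <- if (!length(ch)) G$species[v] else sort(unique(unlist(cl[ch])))
  }
  cl
}

#' Phase 1: basic trees and their costs
#'
#' Enumerates the basic members of the clade family by increasing
#' cardinality and computes, for each, the minimal-cost basic tree via the
#' join-cost recursion: the cost of a partition is the cost of its two basic
#' halves plus `c_div*q1 + c_dup*q2 + c_los1*q3' + c_los2*q3''`. A
#' singleton's basic tree is its one-leaf tree with cost `c_dup * sum_j
#' Par(Gj, s)`. Ties among minimal partitions are broken lexicographically.
#'
#' @param Gjs list of gene `rtree`s.
#' @param P a `clade_family` (default: [default_clade_family()]). Every clade
#'   of every gene tree must be a member.
#' @param costs an [event_costs()] object.
#' @param q_fun census function used for the join term; [q_counts()] here,
#'   [poly_q_counts()] for the polytomy-aware variant.
#' @param singleton_par per-species duplication count for the singleton base;
#'   [par_count()] here, [par_prime()]-based for polytomous input.
#' @return An object of class `basic_table`: list with `entries` (keyed by
#'   clade; each holds `set`, `tree`, `cost`, `parts`), `basic` flags per
#'   family member, `V0`, `P`, `costs`, and `supertree_key` (the key of V0
#'   when basic, else `NA`).
#' @export
phase1 <- function(Gjs, P = default_clade_family(Gjs), costs = event_costs(),
                   q_fun = q_counts,
                   singleton_par = function(G, s) par_count(G, s)) {
  if (inherits(Gjs, "rtree")) Gjs <- list(Gjs)
  stopifnot(inherits(P, "clade_family"))
  # precondition: gene-tree clades belong to P
  pk <- vapply(P$members, set_key, character(1))
  for (G in Gjs)
    for (v in setdiff(seq_len(G$nv), G$superroot)) {
      k <- set_key(clade_of(G, v))
      if (!k %in% pk)
        stop("gene-tree clade not in the clade family: {",
             paste(key_set(k), collapse = ","), "}")
    }
  entries <- new.env(parent = emptyenv())
  basic <- stats::setNames(logical(length(P$members)), pk)
  for (i in seq_along(P$members)) {
    V <- P$members[[i]]; k <- pk[i]
    if (length(V) == 1L) {
      npar <- sum(vapply(Gjs, function(G) singleton_par(G, V), numeric(1)))
      cost <- if (npar == 0) 0 else costs$dup * npar
      assign(k, list(set = V, tree = leaf_tree(V), cost = cost,
                     parts = NULL), envir = entries)
      basic[k] <- TRUE
      next
    }
    best <- Inf; bestparts <- NULL
    for (j in seq_along(P$members)) {
      V1 <- P$members[[j]]
      if (length(V1) >= length(V)) break      # members sorted by cardinality
      k1 <- pk[j]
      if (!basic[k1] || !all(V1 %in% V)) next
      V2 <- setdiff(V, V1)
      k2 <- set_key(V2)
      if (k2 < k1) next                       # each unordered pair once
      if (!isTRUE(basic[k2])) next
      q <- q_fun(Gjs, V1, V2)
      cst <- get(k1, envir = entries)$cost + get(k2, envir = entries)$cost +
        costs$div * q[[1]] + costs$dup * q[[2]] +
        costs$los1 * q[[3]] + costs$los2 * q[[4]]
      if (cst < best) { best <- cst; bestparts <- c(k1, k2) }
    }
    if (!is.null(bestparts)) {
      t1 <- get(bestparts[1], envir = entries)$tree
      t2 <- get(bestparts[2], envir = entries)$tree
      assign(k, list(set = V, tree = join_trees(t1, t2), cost = best,
                     parts = bestparts), envir = entries)
      basic[k] <- TRUE
    }
  }
  v0k <- set_key(P$universe)
  structure(list(entries = entries, basic = basic, V0 = P$universe, P = P,
                 costs = costs,
                 supertree_key = if (isTRUE(basic[v0k])) v0k else NA_character_),
            class = "basic_table")
}

leaf_tree <- function(s) rtree_build(c(NA_integer_, 1L), c(NA_character_, s),
                                     role = "species")

# join two rooted trees under a new common root (superroots dropped)
join_trees <- function(t1, t2) {
  np <- integer(0); nl <- character(0)
  add <- function(parent_new, lab) {
    np[[length(np) + 1L]] <<- parent_new
    nl[[length(nl) + 1L]] <<- lab
    length(np)
  }
  sr <- add(NA_integer_, NA_character_)
  r <- add(sr, NA_character_)
  copy <- function(t, v, parent_new) {
    id <- add(parent_new, t$label[v])
    for (c in t$children[[v]]) copy(t, c, id)
    id
  }
  copy(t1, t1$root, r)
  copy(t2, t2$root, r)
  rtree_build(unlist(np), unlist(nl), role = "species")
}

#' @export
print.basic_table <- function(x, ...) {
  nb <- sum(x$basic)
  cat(sprintf("<basic_table: %d/%d family members basic; V0 %s>\n",
              nb, length(x$basic),
              if (is.na(x$supertree_key)) "NOT basic"
              else sprintf("basic, cost %g", get(x$supertree_key, envir = x$entries)$cost)))
  invisible(x)
}

#' Basic trees of a Phase-1 table
#'
#' @param table a `basic_table`.
#' @param min_leaves keep only trees with at least this many leaves.
#' @return named list of species `rtree`s, keyed by clade.
#' @export
basic_trees <- function(table, min_leaves = 1L) {
  ks <- names(table$basic)[table$basic]
  out <- list()
  for (k in ks) {
    e <- get(k, envir = table$entries)
    if (rt_n_leaves(e$tree) >= min_leaves) out[[k]] <- e$tree
  }
  out
}

#' Cost of a candidate species tree against the basic trees
#'
#' The Phase-2 objective: the summed canonical-reconciliation cost of every
#' basic tree with two or more leaves, pruned to the candidate's species set
#' and mapped into the candidate; basic trees whose pruned form has fewer
#' than two leaves are skipped.
#'
#' @param S a species `rtree` over a subset of V0.
#' @param table a `basic_table` (or a list of trees as produced by
#'   [basic_trees()] / [modified_phase1()]).
#' @param costs an [event_costs()] object.
#' @return a number.
#' @export
tree_cost_against_basics <- function(S, table, costs = event_costs()) {
  trees <- if (inherits(table, "basic_table")) basic_trees(table, 2L) else table
  labs <- rt_species_set(S)
  total <- 0
  for (B in trees) {
    if (rt_n_leaves(B) < 2L) next
    common <- intersect(rt_species_set(B), labs)
    if (length(common) < 2L) next
    Bp <- prune_to(B, labs)
    if (rt_n_leaves(Bp) < 2L) next
    Bg <- Bp; Bg$role <- "gene"; Bg$species <- species_part(Bg$label)
    total <- total + infer_events(Bg, S, costs = costs)$total_cost
  }
  total
}

#' Phase 2: reliability-weighted augmentation
#'
#' Assembles a species tree over V0 from the Phase-1 basic trees. The base
#' step scores every rooted topology over every 3-subset by
#' [tree_cost_against_basics()]; per subset, `c` is the best cost and `c'`
#' the smallest cost strictly greater, giving reliability `R = (c'-c)/c'`;
#' the subset minimizing `c*(2-R)` wins. Each augmentation step tries every
#' unplaced species at every edge (including the root edge); per species,
#' `c` and `c'` are the best and second-best insertion costs; the species
#' minimizing `c*(2-R)` is inserted at its best edge. A species for which
#' `c'` does not exist is marked unreliable and skipped. Ties are resolved
#' by species name, then by insertion-edge id.
#'
#' @param table a `basic_table` from [phase1()] (standard) or a named list of
#'   per-clade trees from [modified_phase1()].
#' @param V0 species universe (defaults to the table's).
#' @param costs an [event_costs()] object.
#' @return list with `tree` (the assembled `rtree`, or `NULL` when no
#'   3-subset has a defined subbasic cost), `trace` (data frame of steps:
#'   added label, c, c', R, score, tree in Newick), `unreliable` (character
#'   vector), and `cost` (the final tree's cost against the basic trees).
#' @export
phase2 <- function(table, V0 = NULL, costs = event_costs()) {
  trees <- if (inherits(table, "basic_table")) basic_trees(table, 2L) else table
  if (is.null(V0)) {
    if (inherits(table, "basic_table")) V0 <- table$V0
    else V0 <- sort(unique(unlist(lapply(table, rt_species_set))))
  }
  V0 <- sort(V0)
  trace <- data.frame(step = integer(0), added = character(0), c = numeric(0),
                      cprime = numeric(0), R = numeric(0), score = numeric(0),
                      tree = character(0))
  if (length(V0) < 3L) stop("phase2 needs at least 3 species")

  # base: best 3-subset
  best <- NULL
  for (trip in utils::combn(V0, 3L, simplify = FALSE)) {
    cands <- enumerate_rooted_trees(trip)
    cc <- vapply(cands, tree_cost_against_basics, numeric(1),
                 table = trees, costs = costs)
    cmin <- min(cc)
    higher <- cc[cc > cmin]
    if (!length(higher)) next               # c' undefined for this subset
    cprime <- min(higher)
    R <- (cprime - cmin) / cprime
    score <- cmin * (2 - R)
    cand <- list(tree = cands[[which.min(cc)]], c = cmin, cprime = cprime,
                 R = R, score = score, label = paste(trip, collapse = "+"))
    if (is.null(best) || score < best$score) best <- cand
  }
  if (is.null(best))
    return(list(tree = NULL, trace = trace, unreliable = character(0),
                cost = NA_real_,
                outcome = "no 3-subset with a defined subbasic cost"))
  S <- best$tree
  trace[1, ] <- list(1L, best$label, best$c, best$cprime, best$R, best$score,
                     write_newick(S))
  unreliable <- character(0)
  step <- 1L
  repeat {
    todo <- setdiff(setdiff(V0, rt_species_set(S)), unreliable)
    if (!length(todo)) break
    pick <- NULL
    for (s in todo) {
      edges <- setdiff(seq_len(S$nv), S$superroot)
      cc <- numeric(length(edges))
      for (i in seq_along(edges)) {
        cc[i] <- tree_cost_against_basics(insert_leaf(S, edges[i], s),
                                          trees, costs)
      }
      cmin <- min(cc)
      higher <- cc[cc > cmin]
      if (!length(higher)) { unreliable <- c(unreliable, s); next }
      cprime <- min(higher)
      R <- (cprime - cmin) / cprime
      score <- cmin * (2 - R)
      if (is.null(pick) || score < pick$score) {
        pick <- list(s = s, edge = edges[which.min(cc)], c = cmin,
                     cprime = cprime, R = R, score = score)
      }
    }
    if (is.null(pick)) break                 # everything left is unreliable
    S <- insert_leaf(S, pick$edge, pick$s)
    step <- step + 1L
    trace[nrow(trace) + 1L, ] <- list(step, pick$s, pick$c, pick$cprime,
                                      pick$R, pick$score, write_newick(S))
  }
  list(tree = S, trace = trace, unreliable = unreliable,
       cost = tree_cost_against_basics(S, trees, costs), outcome = "ok")
}

#' Insert a new leaf on an edge of a species tree
#'
#' Breaks the edge entering `v` with a new vertex whose second child is the
#' new leaf; inserting on the root edge places the new leaf as sister to the
#' whole tree.
#'
#' @param S a species `rtree`.
#' @param v the lower vertex of the target edge.
#' @param s the new species name.
#' @return an `rtree`.
#' @export
insert_leaf <- function(S, v, s) {
  np <- integer(0); nl <- character(0)
  add <- function(parent_new, lab) {
    np[[length(np) + 1L]] <<- parent_new
    nl[[length(nl) + 1L]] <<- lab
    length(np)
  }
  copy <- function(u, parent_new) {
    cur <- parent_new
    if (u == v) {
      mid <- add(parent_new, NA_character_)
      add(mid, s)
      cur <- mid
    }
    id <- add(cur, S$label[u])
    for (c in S$children[[u]]) copy(c, id)
    id
  }
  sr <- add(NA_integer_, NA_character_)
  copy(S$root, sr)
  rtree_build(unlist(np), unlist(nl), role = "species")
}

#' Modified Phase 1 on pruned inputs
#'
#' For every member V of the clade family, prunes every gene tree and every
#' family member to V and runs Phase 1 on the pruned instance; when V is
#' basic there, its basic tree T(V) is recorded. If V is basic for the
#' original instance it is basic for every pruned instance, so this never
#' loses basic sets; it can rescue sets that the unpruned recursion cannot
#' partition. The result feeds [phase2()] directly.
#'
#' @inheritParams phase1
#' @return named list of trees `T(V)` keyed by clade, with attributes
#'   `costs` (per-clade pruned-instance cost).
#' @export
modified_phase1 <- function(Gjs, P = default_clade_family(Gjs),
                            costs = event_costs(), q_fun = q_counts,
                            singleton_par = function(G, s) par_count(G, s)) {
  if (inherits(Gjs, "rtree")) Gjs <- list(Gjs)
  out <- list(); cst <- numeric(0)
  for (V in P$members) {
    Tjs <- list()
    for (G in Gjs) {
      if (!length(intersect(rt_species_set(G), V))) next
      Tjs[[length(Tjs) + 1L]] <- prune_to(G, V)
    }
    if (!length(Tjs)) next
    PV <- lapply(P$members, function(A) intersect(A, V))
    PV <- PV[vapply(PV, length, integer(1)) > 0L]
    tab <- phase1(Tjs, clade_family(V, PV), costs, q_fun, singleton_par)
    k <- set_key(V)
    if (isTRUE(tab$basic[k])) {
      out[[k]] <- get(k, envir = tab$entries)$tree
      cst[k] <- get(k, envir = tab$entries)$cost
    }
  }
  attr(out, "costs") <- cst
  out
}
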