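# Time slices on a species tree.
#
# A *time slice* is a rank on tubes with the monotonicity condition: if tube
# d1 lies below tube d2 then rank(d1) >= rank(d2). Under the uniform-depth
# policy single-child subdivision vertices are inserted so that every
# root-to-leaf path carries the same number h of tubes; the rank of a tube is
# then its depth index, all leaf tubes share rank h-1, and every rank forms a
# full cut of the tree, so tubes of equal rank are contemporaries. Horizontal
# transfers are only legal between distinct tubes of one slice (the relation
# d1 ~ d2).

#' Assign time slices to a binary species tree
#'
#' Inserts subdivision vertices so that every root-to-leaf path has the same
#' number of tubes `h` (the maximal root-to-leaf tube count of the input) and
#' ranks each tube by its depth index: the root tube has rank 0 and all leaf
#' tubes have rank `h - 1`.
#'
#' With `with_outgroup = TRUE` an auxiliary outgroup lineage of `h` chained
#' tubes (one per slice) is attached above the root; a gene lineage that is
#' routed through the outgroup and transferred back models a gene gain.
#'
#' @param S a binary species `rtree`.
#' @param policy slicing policy; only `"uniform-depth"` is provided.
#' @param with_outgroup attach the auxiliary outgroup chain.
#' @return An object of class `sliced_tree`: a list with elements
#'   `tree` (the subdivided `rtree`), `rank` (integer per vertex: rank of the
#'   tube entering that vertex, `NA` for the superroot), `h` (number of
#'   slices), `orig` (for every vertex, the corresponding vertex of the input
#'   tree: a subdivision vertex maps to the lower vertex of the edge it
#'   subdivides; outgroup vertices map to `NA`) and `species_tree` (the
#'   input tree).
#' @export
assign_time_slices <- function(S, policy = "uniform-depth", with_outgroup = FALSE) {
  if (!inherits(S, "rtree") || S$role != "species")
    stop("assign_time_slices expects a species rtree")
  if (!rt_is_binary(S)) stop("species tree must be binary")
  if (!identical(policy, "uniform-depth"))
    stop("unknown slicing policy: ", policy)

  # tube-height below each vertex (own tube included)
  hgt <- integer(S$nv)
  for (v in rt_postorder(S)) {
    ch <- S$children[[v]]
    hgt[v] <- if (!length(ch)) 1L else 1L + max(hgt[ch])
  }
  h <- hgt[S$root]

  np <- integer(0); nl <- character(0); nsub <- logical(0)
  nout <- logical(0); norig <- integer(0); nrank <- integer(0)
  add <- function(parent_new, lab, sub, out, orig, rank) {
    np[[length(np) + 1L]] <<- parent_new
    nl[[length(nl) + 1L]] <<- lab
    nsub[[length(nsub) + 1L]] <<- sub
    nout[[length(nout) + 1L]] <<- out
    norig[[length(norig) + 1L]] <<- orig
    nrank[[length(nrank) + 1L]] <<- rank
    length(np)
  }
  sr <- add(NA_integer_, NA_character_, FALSE, FALSE, S$superroot, NA_integer_)
  rec <- function(v, parent_new, parent_rank) {
    pad <- (h - 1L - parent_rank) - hgt[v]
    cur <- parent_new; r <- parent_rank
    for (i in seq_len(pad)) {
      r <- r + 1L
      cur <- add(cur, NA_character_, TRUE, FALSE, v, r)
    }
    r <- r + 1L
    id <- add(cur, S$label[v], FALSE, FALSE, v, r)
    for (c in S$children[[v]]) rec(c, id, r)
    id
  }
  rec(S$root, sr, -1L)
  if (with_outgroup) {
    cur <- sr
    for (k in seq_len(h)) {
      cur <- add(cur, if (k == h) ".outgroup" else NA_character_,
                 FALSE, TRUE, NA_integer_, k - 1L)
    }
  }
  tree <- rtree_build(unlist(np), unlist(nl), role = "species",
                      subdiv = unlist(nsub), outgroup = unlist(nout))
  structure(list(tree = tree, rank = unlist(nrank), h = h,
                 orig = unlist(norig), species_tree = S),
            class = "sliced_tree")
}

#' @export
print.sliced_tree <- function(x, ...) {
  cat(sprintf("<sliced_tree: %d slices, %d tubes%s> %s\n",
              x$h, x$tree$nv - 1L,
              if (any(x$tree$outgroup)) " (with outgroup)" else "",
              write_newick(x$tree)))
  invisible(x)
}

#' Tubes of a sliced species tree
#'
#' A tube is identified by its lower vertex; the tube set is the full vertex
#' set minus the superroot.
#'
#' @param S0 a `sliced_tree`.
#' @return integer vector of tube ids.
#' @export
sliced_tubes <- function(S0) setdiff(seq_len(S0$tree$nv), S0$tree$superroot)

#' Contemporaneous tubes (the ~ relation)
#'
#' Tubes in the same time slice as `d`, excluding `d` itself.
#'
#' @param S0 a `sliced_tree`.
#' @param d a tube id.
#' @param include_outgroup keep outgroup tubes in the result.
#' @return integer vector of tube ids.
#' @export
slice_mates <- function(S0, d, include_outgroup = TRUE) {
  r <- S0$rank[d]
  out <- setdiff(which(!is.na(S0$rank) & S0$rank == r), d)
  if (!include_outgroup) out <- out[!S0$tree$outgroup[out]]
  sort(out)
}

# nearest original tube of a sliced tube (subdivision tubes report against the
# tube of the original edge they subdivide; outgroup tubes report NA)
slice_orig_tube <- function(S0, d) S0$orig[d]
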