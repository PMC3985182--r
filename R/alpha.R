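# Canonical LCA reconciliation with duplications and losses.
#
# A mapping f assigns every gene-tree vertex to a vertex or tube of the
# species tree; the superroot goes to the root tube and each gene leaf to the
# species leaf of its species. A gene vertex mapped to a tube is a
# *duplication*, a nonleaf vertex mapped to a vertex is a *divergence*, and a
# loss is a pair <e, s> of a gene edge and a species vertex lying strictly
# between the images of the edge's termini. A loss at s is *implicit* when
# the off-path child clade of s contains no species present in the gene tree,
# *explicit* otherwise.

#' Event cost configuration
#'
#' Nonnegative per-event costs; any cost may be `Inf` to forbid the event.
#' The defaults make divergence (the null speciation event) and implicit
#' losses free, so that a gene tree obtainable by pruning the species tree
#' reconciles at zero cost; duplications cost 2 and explicit losses 1, the
#' classic duplication-loss weighting. Divergence must cost less than
#' duplication for the LCA mapping to be the global cost minimum; set
#' `check = FALSE` to override.
#'
#' @param div divergence cost.
#' @param dup duplication cost.
#' @param los1 explicit loss cost.
#' @param los2 implicit loss cost.
#' @param tr_ret cost of a horizontal transfer with retention of the donor copy.
#' @param tr_nor cost of a transfer without retention.
#' @param gain cost of a gene gain (re-entry from the outgroup lineage).
#' @param check enforce `div < dup`.
#' @return An object of class `event_costs`.
#' @export
event_costs <- function(div = 0, dup = 2, los1 = 1, los2 = 0,
                        tr_ret = 3, tr_nor = 3, gain = 1, check = TRUE) {
  x <- list(div = div, dup = dup, los1 = los1, los2 = los2,
            tr_ret = tr_ret, tr_nor = tr_nor, gain = gain)
  bad <- names(x)[vapply(x, function(v) !is.numeric(v) || length(v) != 1 ||
                           is.na(v) || v < 0, logical(1))]
  if (length(bad)) stop("event costs must be nonnegative numbers: ",
                        paste(bad, collapse = ", "))
  if (check && !(div < dup))
    stop("divergence must cost less than duplication (set check = FALSE to override)")
  structure(x, class = "event_costs")
}

#' @export
print.event_costs <- function(x, ...) {
  cat("<event_costs>", paste(names(x), unlist(x), sep = "=", collapse = " "), "\n")
  invisible(x)
}

# A mapping of G into S: per gene vertex, the target species vertex and
# whether the target is the tube above that vertex rather than the vertex.
new_mapping <- function(vertex, is_tube) {
  structure(list(vertex = as.integer(vertex), is_tube = as.logical(is_tube)),
            class = "gs_mapping")
}

#' Canonical LCA mapping of a gene tree into a species tree
#'
#' The superroot maps to the root tube and each leaf to the species leaf of
#' its species. An internal vertex g maps to `LCA(g)` (the LCA in `S` of the
#' clade of g) when every child of g has a strictly smaller LCA; otherwise g
#' maps to the tube entering `LCA(g)` (a duplication). Polytomous gene trees
#' are accepted with the same rule quantified over all children.
#'
#' @param G a gene `rtree`.
#' @param S a binary species `rtree` containing every species of `G`.
#' @return A `gs_mapping`: parallel vectors `vertex` (species vertex per gene
#'   vertex) and `is_tube` (whether the image is the tube above that vertex).
#' @export
compute_alpha <- function(G, S) {
  if (!rt_is_binary(S)) stop("species tree must be binary")
  gl <- rt_leaves(G)
  missing <- setdiff(G$species[gl], rt_species_set(S))
  if (length(missing))
    stop("gene leaf species not in species tree: ", missing[1])
  leafmap <- stats::setNames(rt_leaves(S), S$species[rt_leaves(S)])
  lca <- integer(G$nv)
  vertex <- integer(G$nv); is_tube <- logical(G$nv)
  for (g in rt_postorder(G)) {
    ch <- G$children[[g]]
    if (!length(ch)) {                      # gene leaf
      lca[g] <- leafmap[[G$species[g]]]
      vertex[g] <- lca[g]; is_tube[g] <- FALSE
    } else if (g == G$superroot) {
      vertex[g] <- S$root; is_tube[g] <- TRUE   # root tube
      lca[g] <- lca[ch[1]]
    } else {
      cur <- lca[ch[1]]
      for (c in ch[-1]) while (!rt_weakly_below(S, lca[c], cur))
        cur <- S$parent[cur]
      lca[g] <- cur
      vertex[g] <- cur
      is_tube[g] <- any(lca[ch] == cur)
    }
  }
  new_mapping(vertex, is_tube)
}

#' Validate a mapping of G into S
#'
#' Checks the mapping invariants: the superroot maps to the root tube, each
#' leaf to its species leaf, images are order-preserving along gene edges,
#' and a vertex mapped onto a species vertex has its children mapped into
#' distinct child subtrees (the divergence side condition).
#'
#' @param G,S gene and species `rtree`s.
#' @param f a `gs_mapping` total on the vertices of `G`.
#' @return `TRUE` if valid, otherwise a character string naming the first
#'   violated condition and the offending vertex.
#' @export
validate_mapping <- function(G, S, f) {
  if (length(f$vertex) != G$nv) return("mapping not total on gene vertices")
  if (!(f$vertex[G$superroot] == S$root && f$is_tube[G$superroot]))
    return(sprintf("superroot: must map to the root tube (vertex %d)", G$superroot))
  leafmap <- stats::setNames(rt_leaves(S), S$species[rt_leaves(S)])
  for (g in rt_leaves(G)) {
    if (f$is_tube[g] || f$vertex[g] != leafmap[[G$species[g]]])
      return(sprintf("leaf: vertex %d must map to species leaf '%s'", g, G$species[g]))
  }
  for (g in seq_len(G$nv)) {
    ch <- G$children[[g]]
    if (!length(ch)) next
    for (c in ch) {
      if (!pos_weakly_below(S, f$vertex[c], f$is_tube[c], f$vertex[g], f$is_tube[g]))
        return(sprintf("order: child %d of vertex %d maps above its parent's image", c, g))
    }
    if (!f$is_tube[g] && g != G$superroot) {
      s <- f$vertex[g]
      side <- integer(length(ch))
      for (i in seq_along(ch)) {
        c <- ch[i]
        if (f$vertex[c] == s)
          return(sprintf("divergence side condition: child %d of vertex %d maps onto the same vertex", c, g))
        sub <- S$children[[s]][vapply(S$children[[s]], function(x)
          rt_weakly_below(S, f$vertex[c], x), logical(1))]
        if (!length(sub))
          return(sprintf("order: child %d of vertex %d not below image vertex", c, g))
        side[i] <- sub[1]
      }
      if (anyDuplicated(side))
        return(sprintf("divergence side condition: children of vertex %d map into one child subtree", g))
    }
  }
  TRUE
}

#' Infer duplication, divergence and loss events of a mapping
#'
#' Applies the event definitions to a valid mapping: duplications are gene
#' vertices imaged in tubes, divergences are nonleaf vertices imaged in
#' vertices, and losses are (gene edge, species vertex) pairs with the vertex
#' strictly between the images of the edge's termini, classified explicit or
#' implicit by whether the off-path child clade contains species present in
#' the gene tree. Transfers and gains are never produced here (see
#' [best_scenario()] for the transfer-aware engine).
#'
#' @param G,S gene and species `rtree`s.
#' @param f a valid `gs_mapping` (defaults to [compute_alpha()]).
#' @param costs an [event_costs()] object.
#' @param validate check `f` with [validate_mapping()] first; disable only
#'   for mappings known valid by construction (e.g. in enumeration loops).
#' @return An object of class `event_inventory`: a list with data frames
#'   `duplications` (gene vertex, tube), `divergences` (gene vertex, species
#'   vertex), `losses` (gene edge, species vertex, explicit flag), empty
#'   `transfers`/`gains`, and `total_cost`.
#' @export
infer_events <- function(G, S, f = compute_alpha(G, S), costs = event_costs(),
                         validate = TRUE) {
  if (validate) {
    ok <- validate_mapping(G, S, f)
    if (!isTRUE(ok)) stop("invalid mapping: ", ok)
  }
  speciesG <- rt_species_set(G)
  has_sp <- logical(S$nv)
  for (v in rt_postorder(S)) {
    ch <- S$children[[v]]
    has_sp[v] <- if (!length(ch)) isTRUE(S$species[v] %in% speciesG)
                 else any(has_sp[ch])
  }

  dup_g <- integer(0); dup_d <- integer(0)
  div_g <- integer(0); div_s <- integer(0)
  los_e <- integer(0); los_s <- integer(0); los_x <- logical(0)

  for (g in seq_len(G$nv)) {
    if (g == G$superroot) next
    if (f$is_tube[g]) { dup_g <- c(dup_g, g); dup_d <- c(dup_d, f$vertex[g]) }
    else if (length(G$children[[g]])) { div_g <- c(div_g, g); div_s <- c(div_s, f$vertex[g]) }
  }
  for (e in seq_len(G$nv)) {                # edge identified by lower vertex
    if (e == G$superroot) next
    p <- G$parent[e]
    lowv <- f$vertex[e]
    s <- S$parent[lowv]                     # first vertex strictly above f(e+)
    topv <- f$vertex[p]; toptube <- f$is_tube[p]
    while (!is.na(s) && s != S$superroot &&
           pos_strictly_below(S, s, FALSE, topv, toptube)) {
      onpath <- S$children[[s]][vapply(S$children[[s]], function(x)
        rt_weakly_below(S, lowv, x), logical(1))][1]
      offpath <- setdiff(S$children[[s]], onpath)
      los_e <- c(los_e, e); los_s <- c(los_s, s)
      los_x <- c(los_x, any(has_sp[offpath]))
      s <- S$parent[s]
    }
  }
  inv <- structure(list(
    duplications = data.frame(gene_vertex = dup_g, tube = dup_d),
    divergences = data.frame(gene_vertex = div_g, species_vertex = div_s),
    losses = data.frame(gene_edge = los_e, species_vertex = los_s, explicit = los_x),
    transfers = data.frame(gene_edge = integer(0), donor = integer(0),
                           recipient = integer(0), retention = logical(0)),
    gains = data.frame(gene_edge = integer(0), reentry_tube = integer(0)),
    total_cost = NA_real_
  ), class = "event_inventory")
  inv$total_cost <- event_cost(inv, costs)
  inv
}

#' Total cost of an event inventory
#'
#' Weighted sum of the inventory's events under the given costs; an `Inf`
#' cost on a present event type propagates to `Inf`.
#'
#' @param inv an `event_inventory`.
#' @param costs an [event_costs()] object.
#' @return a number (possibly `Inf`).
#' @export
event_cost <- function(inv, costs = event_costs()) {
  n_expl <- sum(inv$losses$explicit)
  n_impl <- sum(!inv$losses$explicit)
  tr <- inv$transfers
  wsum <- function(n, c) if (n == 0L) 0 else n * c   # 0 * Inf must stay 0
  wsum(nrow(inv$duplications), costs$dup) +
    wsum(nrow(inv$divergences), costs$div) +
    wsum(n_expl, costs$los1) + wsum(n_impl, costs$los2) +
    wsum(sum(tr$retention), costs$tr_ret) +
    wsum(sum(!tr$retention), costs$tr_nor) +
    wsum(nrow(inv$gains), costs$gain)
}

#' @export
print.event_inventory <- function(x, ...) {
  cat(sprintf(
    "<event_inventory: %d dup, %d div, %d expl loss, %d impl loss, %d transfer, %d gain; cost %g>\n",
    nrow(x$duplications), nrow(x$divergences), sum(x$losses$explicit),
    sum(!x$losses$explicit), nrow(x$transfers), nrow(x$gains), x$total_cost))
  invisible(x)
}

#' Enumerate every valid mapping of G into S
#'
#' Exhaustive-oracle enumeration of all mappings satisfying the mapping
#' definition, each exactly once; the canonical mapping is always among
#' them. Guarded to small instances.
#'
#' @param G,S gene and species `rtree`s (`G` binary).
#' @param guard maximal combined leaf count (default 12).
#' @return list of `gs_mapping` objects.
#' @export
enumerate_mappings <- function(G, S, guard = 12L) {
  if (rt_n_leaves(G) + rt_n_leaves(S) > guard)
    stop("enumerate_mappings is an oracle for test scale: ",
         "combined leaf count exceeds ", guard)
  leafmap <- stats::setNames(rt_leaves(S), S$species[rt_leaves(S)])
  order_g <- setdiff(rt_postorder(G), G$superroot)
  positions <- rbind(
    data.frame(vertex = setdiff(seq_len(S$nv), S$superroot), is_tube = FALSE),
    data.frame(vertex = setdiff(seq_len(S$nv), S$superroot), is_tube = TRUE))
  positions <- positions[order(positions$vertex, positions$is_tube), ]
  out <- list()
  vertex <- integer(G$nv); is_tube <- logical(G$nv)
  vertex[G$superroot] <- S$root; is_tube[G$superroot] <- TRUE

  ok_for <- function(g, v, tube) {
    ch <- G$children[[g]]
    for (c in ch) {
      if (!pos_weakly_below(S, vertex[c], is_tube[c], v, tube)) return(FALSE)
    }
    if (!tube) {
      side <- integer(length(ch))
      for (i in seq_along(ch)) {
        c <- ch[i]
        if (vertex[c] == v) return(FALSE)
        sub <- S$children[[v]][vapply(S$children[[v]], function(x)
          rt_weakly_below(S, vertex[c], x), logical(1))]
        if (!length(sub)) return(FALSE)
        side[i] <- sub[1]
      }
      if (anyDuplicated(side)) return(FALSE)
    }
    TRUE
  }
  rec <- function(i) {
    if (i > length(order_g)) {
      out[[length(out) + 1L]] <<- new_mapping(vertex, is_tube)
      return(invisible(NULL))
    }
    g <- order_g[i]
    if (!length(G$children[[g]])) {        # leaf: forced
      vertex[g] <<- leafmap[[G$species[g]]]; is_tube[g] <<- FALSE
      rec(i + 1L)
      return(invisible(NULL))
    }
    for (k in seq_len(nrow(positions))) {
      v <- positions$vertex[k]; tube <- positions$is_tube[k]
      if (ok_for(g, v, tube)) {
        vertex[g] <<- v; is_tube[g] <<- tube
        rec(i + 1L)
      }
    }
  }
  rec(1L)
  out
}

#' Number of in-paralog duplications forced in a leaf tube
#'
#' `Par(G, s)`: the total number of nonleaf vertices over all maximal
#' subtrees of `G` whose clade is the singleton `{s}`. Under the canonical
#' mapping this equals the number of duplications located in the leaf tube
#' of species `s`.
#'
#' @param G a gene `rtree`.
#' @param s a species name.
#' @return integer.
#' @export
par_count <- function(G, s) {
  cl <- vector("list", G$nv)
  n_int <- integer(G$nv)   # internal vertices within the subtree
  total <- 0L
  for (v in rt_postorder(G)) {
    ch <- G$children[[v]]
    if (!length(ch)) { cl[[v]] <- G$species[v]; n_int[v] <- 0L; next }
    cl[[v]] <- sort(unique(unlist(cl[ch])))
    n_int[v] <- if (v == G$superroot) sum(n_int[ch]) else 1L + sum(n_int[ch])
  }
  # maximality: clade(v) == {s} and the parent's clade is larger
  for (v in seq_len(G$nv)) {
    if (v == G$superroot) next
    if (!identical(cl[[v]], s)) next
    p <- G$parent[v]
    if (p == G$superroot || !identical(cl[[p]], s)) total <- total + n_int[v]
  }
  total
}
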