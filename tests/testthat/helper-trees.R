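# Shared fixtures and small conveniences.

gt <- function(nwk) parse_newick(nwk, "gene")
st <- function(nwk) parse_newick(nwk, "species")

# species tree pruned to a subset, recast as a gene tree
pruned_gene <- function(S, keep) {
  g <- prune_to(S, keep)
  g$role <- "gene"
  g$species <- species_part(g$label)
  g
}

# natural order on positions (vertex v, or the tube above v when tube=TRUE)
pos_wb <- function(S, v1, tube1, v2, tube2) {
  if (v1 == v2) return(tube1 == tube2 || (!tube1 && tube2))
  rt_weakly_below(S, v1, v2)
}

# canonical newick: children sorted recursively, for topology comparison
canon_newick <- function(t) {
  rec <- function(v) {
    ch <- t$children[[v]]
    if (!length(ch)) return(t$label[v])
    parts <- sort(vapply(ch, rec, character(1)))
    if (length(parts) == 1L) return(parts)
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(t$root), ";")
}

# canonical newick over species names (gene ids stripped)
canon_by_species <- function(t) {
  rec <- function(v) {
    ch <- t$children[[v]]
    if (!length(ch)) return(t$species[v])
    parts <- sort(vapply(ch, rec, character(1)))
    if (length(parts) == 1L) return(parts)
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(t$root), ";")
}

# multiset signature of an inventory's events, keyed by the clade of the
# location so it is comparable across different host trees
event_signature <- function(inv, S, use_orig = FALSE) {
  key <- function(v) paste(clade_of(S, v), collapse = "+")
  dup <- if (use_orig) inv$duplications$tube_orig else inv$duplications$tube
  div <- if (use_orig) inv$divergences$species_vertex_orig else inv$divergences$species_vertex
  los <- if (use_orig) inv$losses$species_vertex_orig else inv$losses$species_vertex
  # unsorted, aligned with rbind(duplications, divergences, losses) order;
  # sort at the comparison site
  c(
    vapply(dup, function(v) paste0("dup@", key(v)), character(1)),
    vapply(div, function(v) paste0("div@", key(v)), character(1)),
    if (nrow(inv$losses))
      mapply(function(v, x) paste0("los", if (x) "X" else "I", "@", key(v)),
             los, inv$losses$explicit, USE.NAMES = FALSE)
    else character(0)
  )
}

# every distinct labeled gene tree with n_leaves leaves over the species pool
# (species may repeat -> paralogs), deduplicated by canonical topology
all_gene_trees <- function(species, n_leaves) {
  shapes <- if (n_leaves == 1L) list(parse_newick("L1;", "species"))
            else enumerate_rooted_trees(paste0("L", seq_len(n_leaves)))
  assigns <- expand.grid(rep(list(species), n_leaves), stringsAsFactors = FALSE)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (sh in shapes) {
    leaves <- rt_leaves(sh)
    ord <- order(as.integer(sub("L", "", sh$label[leaves])))
    leaves <- leaves[ord]
    for (i in seq_len(nrow(assigns))) {
      g <- sh
      g$label[leaves] <- as.character(assigns[i, ])
      g$role <- "gene"
      g$species <- species_part(g$label)
      k <- canon_newick(g)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        out[[length(out) + 1L]] <- g
      }
    }
  }
  out
}

# all species trees (every topology) over every subset of `pool` of size >= 2
all_species_trees <- function(pool) {
  out <- list()
  for (k in 2:length(pool)) {
    for (sub in utils::combn(pool, k, simplify = FALSE)) {
      for (s in enumerate_rooted_trees(sub)) out[[length(out) + 1L]] <- s
    }
  }
  out
}
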