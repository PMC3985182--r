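# Minimum-cost evolutionary scenarios on a time-sliced species tree.
#
# For every pair <e, d> of a gene edge e and a species tube d, an *inner
# tree* describes one alternative evolution of lineage e inside tube d; its
# cost is defined by induction over pairs ordered by (gene edge postorder,
# decreasing tube rank). The minimal inner-tree cost at the root pair
# <e0, d0> is the scenario cost; backtracking the minimizing choices yields
# the scenario: a copy of G with inserted single-child vertices marking
# transfer departures/arrivals, its mapping, and the event inventory.
#
# Rules for a pair <e, d> (base: leaf edge in a leaf tube, costing 0 when the
# species match and one transfer without retention otherwise):
#   1   d has a single child tube: the lineage enters the next tube.
#   2   d branches: the lineage survives in one child tube, a loss in the other.
#   3   e duplicates inside d.
#   4   e diverges at the branching vertex of d (+ swapped child assignment).
#   5   e duplicates in d, one copy transfers to a contemporary tube d',
#       the donor copy is retained (+ swap).
#   6.x e transfers without retention into a contemporary tube d' and there
#       enters the next tube (6.1), survives one side of a branching (6.2),
#       duplicates (6.3), diverges (6.4), or duplicates-and-retransfers into
#       a third contemporary tube d'' (6.5).
#
# Gene gain is modelled by routing a lineage through an auxiliary outgroup
# chain (see assign_time_slices(with_outgroup = TRUE)): transfers leaving an
# outgroup tube are charged the gain cost, the extra root split into the
# outgroup (rule 3') is free, and duplications in outgroup tubes, losses at
# the root tube and the divergence at the root vertex are free.

#' Fill the inner-tree cost table
#'
#' Computes the minimal inner-tree cost for every pair of a gene edge and a
#' species tube, in the well-founded order (gene edges leaf-to-root; within
#' an edge, tubes by decreasing rank), together with the minimizing rule
#' choice for backtracking. Ties are broken by a fixed rule precedence
#' (4, 2, 1, 3, 5, 6.x) and then by smallest auxiliary tube ids, so the
#' backtracked scenario is deterministic; preferring descent (rules 2 and 1)
#' over duplication (rule 3) localizes tied events as low as the canonical
#' LCA mapping does, so the transfer-free scenario reproduces its event
#' multiset exactly.
#'
#' @param G a binary gene `rtree`.
#' @param S0 a `sliced_tree` (with the outgroup chain when `gain = TRUE`).
#' @param costs an [event_costs()] object.
#' @param gain enable the gain-via-outgroup modifications.
#' @return An object of class `inner_table`: cost matrix indexed by
#'   `[gene vertex, tube]`, choice records, and the inputs.
#' @export
build_inner_table <- function(G, S0, costs = event_costs(), gain = FALSE) {
  if (!inherits(S0, "sliced_tree"))
    stop("S0 must be a sliced species tree (see assign_time_slices)")
  if (!rt_is_binary(G)) stop("gene tree must be binary; binarize first")
  if (gain && !any(S0$tree$outgroup))
    stop("gain = TRUE requires a sliced tree built with with_outgroup = TRUE")
  St <- S0$tree
  missing <- setdiff(rt_species_set(G), rt_species_set(St))
  if (length(missing)) stop("gene leaf species not in species tree: ", missing[1])

  tubes <- sliced_tubes(S0)
  d0 <- St$root
  speciesG <- rt_species_set(G)
  leafmap <- stats::setNames(rt_leaves(St), St$species[rt_leaves(St)])
  # species content below each sliced vertex (outgroup leaves excluded)
  has_sp <- vapply(seq_len(St$nv), function(v)
    length(intersect(St$species[rt_descendant_leaves(St, v)], speciesG)) > 0L,
    logical(1))
  loss_cost <- function(lost_tube, at_tube) {
    if (gain && at_tube == d0) return(c(0, has_sp[lost_tube]))
    c(if (has_sp[lost_tube]) costs$los1 else costs$los2, has_sp[lost_tube])
  }
  dup_cost <- function(d) if (gain && St$outgroup[d]) 0 else costs$dup
  div_cost <- function(d) if (gain && d == d0) 0 else costs$div
  trn_cost <- function(donor) if (gain && St$outgroup[donor]) costs$gain else costs$tr_nor
  trr_cost <- function(donor) if (gain && St$outgroup[donor]) costs$gain else costs$tr_ret
  # upper outgroup tube (rule 3')
  dstar <- if (gain) which(St$outgroup & !is.na(S0$rank) & S0$rank == 0L) else integer(0)

  nvG <- G$nv; nvS <- St$nv
  cost <- matrix(NA_real_, nrow = nvG, ncol = nvS)
  choice <- vector("list", nvG * nvS)
  dim(choice) <- c(nvG, nvS)

  edges <- setdiff(rt_postorder(G), G$superroot)
  tubes_by_rank <- tubes[order(-S0$rank[tubes], tubes)]

  for (e in edges) {
    e_leaf <- !length(G$children[[e]])
    ech <- G$children[[e]]
    for (d in tubes_by_rank) {
      dch <- St$children[[d]]
      d_leaf <- !length(dch)
      best <- Inf; bestch <- NULL
      consider <- function(cst, rec) {
        if (is.null(bestch) || cst < best) { best <<- cst; bestch <<- rec }
      }
      mates <- slice_mates(S0, d, include_outgroup = !gain)

      if (e_leaf && d_leaf) {
        dp <- leafmap[[G$species[e]]]
        cst <- if (d == dp) 0 else trn_cost(d)
        consider(cst, list(rule = "base", dprime = dp))
      } else {
        # tie precedence: 4, then descent (2/1), then 3, 3', 5, 6.x — descent
        # before duplication keeps tied events as low as the LCA mapping's
        if (!e_leaf && length(dch) == 2L) {
          for (sw in c(FALSE, TRUE)) {
            a <- if (sw) ech[2] else ech[1]; b <- if (sw) ech[1] else ech[2]
            consider(cost[a, dch[1]] + cost[b, dch[2]] + div_cost(d),
                     list(rule = "4", ea = a, eb = b, da = dch[1], db = dch[2]))
          }
        }
        if (length(dch) == 2L) {
          for (i in 1:2) {
            lc <- loss_cost(dch[3 - i], d)
            consider(cost[e, dch[i]] + lc[1],
                     list(rule = "2", keep = dch[i], lost = dch[3 - i],
                          explicit = as.logical(lc[2])))
          }
        }
        if (length(dch) == 1L)
          consider(cost[e, dch[1]], list(rule = "1", dnext = dch[1]))
        if (!e_leaf)
          consider(cost[ech[1], d] + cost[ech[2], d] + dup_cost(d),
                   list(rule = "3"))
        if (gain && !e_leaf && d == d0) {
          for (sw in c(FALSE, TRUE)) {
            a <- if (sw) ech[2] else ech[1]; b <- if (sw) ech[1] else ech[2]
            consider(cost[a, d0] + cost[b, dstar],
                     list(rule = "3p", ea = a, eb = b, dstar = dstar))
          }
        }
        if (!e_leaf) {
          for (dp in mates) {
            for (sw in c(FALSE, TRUE)) {
              a <- if (sw) ech[2] else ech[1]; b <- if (sw) ech[1] else ech[2]
              consider(cost[a, d] + cost[b, dp] + trr_cost(d),
                       list(rule = "5", stay = a, move = b, dprime = dp))
            }
          }
        }
        for (dp in mates) {
          dpch <- St$children[[dp]]
          if (length(dpch) == 1L)
            consider(cost[e, dpch[1]] + trn_cost(d),
                     list(rule = "6.1", dprime = dp, dnext = dpch[1]))
          if (length(dpch) == 2L) {
            for (i in 1:2) {
              lc <- loss_cost(dpch[3 - i], dp)
              consider(cost[e, dpch[i]] + trn_cost(d) + lc[1],
                       list(rule = "6.2", dprime = dp, keep = dpch[i],
                            lost = dpch[3 - i], explicit = as.logical(lc[2])))
            }
          }
          if (!e_leaf) {
            consider(cost[ech[1], dp] + cost[ech[2], dp] + trn_cost(d) + dup_cost(dp),
                     list(rule = "6.3", dprime = dp))
            if (length(dpch) == 2L) {
              for (sw in c(FALSE, TRUE)) {
                a <- if (sw) ech[2] else ech[1]; b <- if (sw) ech[1] else ech[2]
                consider(cost[a, dpch[1]] + cost[b, dpch[2]] + trn_cost(d) + div_cost(dp),
                         list(rule = "6.4", dprime = dp, ea = a, eb = b,
                              da = dpch[1], db = dpch[2]))
              }
            }
            for (ds in setdiff(slice_mates(S0, dp, include_outgroup = !gain), d)) {
              for (sw in c(FALSE, TRUE)) {
                a <- if (sw) ech[2] else ech[1]; b <- if (sw) ech[1] else ech[2]
                consider(cost[a, dp] + cost[b, ds] + trn_cost(d) + trr_cost(dp),
                         list(rule = "6.5", dprime = dp, dsecond = ds,
                              stay = a, move = b))
              }
            }
          }
        }
      }
      cost[e, d] <- best
      choice[[e, d]] <- bestch
    }
  }
  structure(list(cost = cost, choice = choice, G = G, S0 = S0,
                 costs = costs, gain = gain, d0 = d0,
                 root_pair = c(G$root, d0)),
            class = "inner_table")
}

#' @export
print.inner_table <- function(x, ...) {
  cat(sprintf("<inner_table: %d gene edges x %d tubes; cost at root pair %g>\n",
              length(setdiff(seq_len(x$G$nv), x$G$superroot)),
              length(sliced_tubes(x$S0)),
              x$cost[x$root_pair[1], x$root_pair[2]]))
  invisible(x)
}

#' Backtrack the minimum-cost scenario from an inner-tree table
#'
#' Reconstructs, from the minimizing choices at the root pair, the scenario:
#' a copy of the gene tree with inserted single-child vertices (on an edge
#' carrying n insertions, n even encodes n/2 transfers without retention, n
#' odd one transfer with retention plus (n-1)/2 without), the mapping of
#' that tree into the sliced species tree, and the localized event inventory.
#' Transfers leaving an outgroup tube are reported as gains.
#'
#' @param table an `inner_table` from [build_inner_table()].
#' @return An object of class `scenario`: list with `gene_tree_prime`,
#'   `mapping`, `events` (an `event_inventory` whose locations are sliced-tree
#'   ids, with `*_orig` columns giving the nearest vertex of the original
#'   species tree), and `total_cost`.
#' @export
best_scenario <- function(table) {
  G <- table$G; S0 <- table$S0; St <- S0$tree
  total <- table$cost[table$root_pair[1], table$root_pair[2]]
  if (!is.finite(total))
    stop("no feasible scenario under these costs (infinite root entry)")

  mapv <- integer(G$nv); mapt <- logical(G$nv)
  mapv[G$superroot] <- table$d0; mapt[G$superroot] <- TRUE
  ins <- vector("list", G$nv)              # per-edge insertions, top-down
  ev <- new.env()
  ev$dup <- list(); ev$div <- list(); ev$los <- list()
  ev$tr <- list(); ev$gn <- list()

  add_ins <- function(e, v, tube) ins[[e]] <<- c(ins[[e]], list(c(v, tube)))
  rec_transfer <- function(e, donor, recipient, retention) {
    if (table$gain && St$outgroup[donor])
      ev$gn[[length(ev$gn) + 1L]] <- c(e, recipient)
    else
      ev$tr[[length(ev$tr) + 1L]] <- c(e, donor, recipient, retention)
  }

  walk <- function(e, d) {
    ch <- table$choice[[e, d]]
    switch(ch$rule,
      base = {
        if (ch$dprime != d) {
          rec_transfer(e, d, ch$dprime, FALSE)
          add_ins(e, d, TRUE); add_ins(e, ch$dprime, TRUE)
        }
        mapv[e] <<- ch$dprime; mapt[e] <<- FALSE
      },
      "1" = walk(e, ch$dnext),
      "2" = {
        ev$los[[length(ev$los) + 1L]] <- c(e, d, ch$explicit)
        walk(e, ch$keep)
      },
      "3" = {
        mapv[e] <<- d; mapt[e] <<- TRUE
        ev$dup[[length(ev$dup) + 1L]] <- c(e, d)
        for (c in G$children[[e]]) walk(c, d)
      },
      "3p" = {
        mapv[e] <<- d; mapt[e] <<- TRUE     # free split into the outgroup
        walk(ch$ea, d)
        add_ins(ch$eb, ch$dstar, TRUE)
        walk(ch$eb, ch$dstar)
      },
      "4" = {
        mapv[e] <<- d; mapt[e] <<- FALSE    # d_+ is identified by d itself
        ev$div[[length(ev$div) + 1L]] <- c(e, d)
        walk(ch$ea, ch$da); walk(ch$eb, ch$db)
      },
      "5" = {
        mapv[e] <<- d; mapt[e] <<- TRUE
        rec_transfer(ch$move, d, ch$dprime, TRUE)
        walk(ch$stay, d)
        add_ins(ch$move, ch$dprime, TRUE)
        walk(ch$move, ch$dprime)
      },
      "6.1" = {
        rec_transfer(e, d, ch$dprime, FALSE)
        add_ins(e, d, TRUE); add_ins(e, ch$dprime, TRUE)
        walk(e, ch$dnext)
      },
      "6.2" = {
        rec_transfer(e, d, ch$dprime, FALSE)
        add_ins(e, d, TRUE); add_ins(e, ch$dprime, TRUE)
        ev$los[[length(ev$los) + 1L]] <- c(e, ch$dprime, ch$explicit)
        walk(e, ch$keep)
      },
      "6.3" = {
        rec_transfer(e, d, ch$dprime, FALSE)
        add_ins(e, d, TRUE); add_ins(e, ch$dprime, TRUE)
        mapv[e] <<- ch$dprime; mapt[e] <<- TRUE
        ev$dup[[length(ev$dup) + 1L]] <- c(e, ch$dprime)
        for (c in G$children[[e]]) walk(c, ch$dprime)
      },
      "6.4" = {
        rec_transfer(e, d, ch$dprime, FALSE)
        add_ins(e, d, TRUE); add_ins(e, ch$dprime, TRUE)
        mapv[e] <<- ch$dprime; mapt[e] <<- FALSE
        ev$div[[length(ev$div) + 1L]] <- c(e, ch$dprime)
        walk(ch$ea, ch$da); walk(ch$eb, ch$db)
      },
      "6.5" = {
        rec_transfer(e, d, ch$dprime, FALSE)
        add_ins(e, d, TRUE); add_ins(e, ch$dprime, TRUE)
        mapv[e] <<- ch$dprime; mapt[e] <<- TRUE
        rec_transfer(ch$move, ch$dprime, ch$dsecond, TRUE)
        walk(ch$stay, ch$dprime)
        add_ins(ch$move, ch$dsecond, TRUE)
        walk(ch$move, ch$dsecond)
      },
      stop("internal error: unknown rule tag ", ch$rule)
    )
    invisible(NULL)
  }
  walk(table$root_pair[1], table$root_pair[2])

  # assemble G' with the inserted single-child vertices
  np <- integer(0); nl <- character(0); nsub <- logical(0)
  mv <- integer(0); mt <- logical(0); orig_g <- integer(0)
  add <- function(parent_new, lab, sub, v, tube, og) {
    np[[length(np) + 1L]] <<- parent_new
    nl[[length(nl) + 1L]] <<- lab
    nsub[[length(nsub) + 1L]] <<- sub
    mv[[length(mv) + 1L]] <<- v
    mt[[length(mt) + 1L]] <<- tube
    orig_g[[length(orig_g) + 1L]] <<- og
    length(np)
  }
  build <- function(v, parent_new) {
    cur <- parent_new
    if (v != G$superroot)
      for (rec in ins[[v]])
        cur <- add(cur, NA_character_, TRUE, rec[1], as.logical(rec[2]), NA_integer_)
    id <- add(cur, G$label[v],
              if (v == G$superroot) FALSE else FALSE, mapv[v], mapt[v], v)
    for (c in G$children[[v]]) build(c, id)
    id
  }
  build(G$superroot, NA_integer_)
  Gp <- rtree_build(unlist(np), unlist(nl), role = "gene", subdiv = unlist(nsub))

  to_df <- function(lst, cols) {
    if (!length(lst)) {
      df <- as.data.frame(stats::setNames(rep(list(integer(0)), length(cols)), cols))
      return(df)
    }
    df <- as.data.frame(do.call(rbind, lst))
    names(df) <- cols
    df
  }
  dup <- to_df(ev$dup, c("gene_vertex", "tube"))
  div <- to_df(ev$div, c("gene_vertex", "species_vertex"))
  los <- to_df(ev$los, c("gene_edge", "species_vertex", "explicit"))
  los$explicit <- as.logical(los$explicit)
  tr <- to_df(ev$tr, c("gene_edge", "donor", "recipient", "retention"))
  tr$retention <- as.logical(tr$retention)
  gn <- to_df(ev$gn, c("gene_edge", "reentry_tube"))
  dup$tube_orig <- S0$orig[dup$tube]
  div$species_vertex_orig <- S0$orig[div$species_vertex]
  los$species_vertex_orig <- S0$orig[los$species_vertex]

  events <- structure(list(duplications = dup, divergences = div, losses = los,
                           transfers = tr, gains = gn, total_cost = total),
                      class = "event_inventory")
  structure(list(gene_tree_prime = Gp,
                 mapping = new_mapping(mv, mt),
                 gp_orig_vertex = unlist(orig_g),
                 events = events, total_cost = total,
                 S0 = S0, costs = table$costs, gain = table$gain),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario: cost %g>\n", x$total_cost))
  print(x$events)
  invisible(x)
}

#' Tabulate a scenario's events per species-tree location
#'
#' @param sc a `scenario` from [best_scenario()].
#' @return list with `event_counts` (per original species-tree vertex:
#'   duplications, divergences, explicit and implicit losses, gains) and
#'   `transfer_arcs` (donor, recipient, slice rank, retention flag).
#' @export
scenario_report <- function(sc) {
  if (!inherits(sc, "scenario")) stop("not a scenario")
  S <- sc$S0$species_tree
  if (rt_n_leaves(sc$gene_tree_prime) == 0L) stop("empty gene tree")
  locs <- setdiff(seq_len(S$nv), S$superroot)
  cnt <- data.frame(
    species_vertex = locs,
    duplications = vapply(locs, function(v)
      sum(sc$events$duplications$tube_orig == v, na.rm = TRUE), numeric(1)),
    divergences = vapply(locs, function(v)
      sum(sc$events$divergences$species_vertex_orig == v, na.rm = TRUE), numeric(1)),
    explicit_losses = vapply(locs, function(v)
      sum(sc$events$losses$species_vertex_orig == v & sc$events$losses$explicit,
          na.rm = TRUE), numeric(1)),
    implicit_losses = vapply(locs, function(v)
      sum(sc$events$losses$species_vertex_orig == v & !sc$events$losses$explicit,
          na.rm = TRUE), numeric(1)),
    gains = vapply(locs, function(v)
      sum(sc$S0$orig[sc$events$gains$reentry_tube] == v, na.rm = TRUE), numeric(1))
  )
  tr <- sc$events$transfers
  arcs <- data.frame(donor = tr$donor, recipient = tr$recipient,
                     slice = sc$S0$rank[tr$donor], retention = tr$retention)
  list(event_counts = cnt, transfer_arcs = arcs)
}
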