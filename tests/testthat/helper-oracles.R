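# Independent brute-force oracles. These re-derive quantities from the
# definitions by plain recursion/enumeration, without the package's dynamic
# programs, and are only run at test scale.

# Minimal inner-tree cost for <e, d> by direct recursion over the rule set
# (no memoization, no tables). `e` is a gene vertex (edge id), `d` a tube of
# the sliced tree.
oracle_inner_cost <- function(G, S0, costs, gain = FALSE) {
  St <- S0$tree
  d0 <- St$root
  speciesG <- rt_species_set(G)
  leafmap <- stats::setNames(rt_leaves(St), St$species[rt_leaves(St)])
  has_sp <- vapply(seq_len(St$nv), function(v)
    length(intersect(St$species[rt_descendant_leaves(St, v)], speciesG)) > 0L,
    logical(1))
  loss_of <- function(lost, at) {
    if (gain && at == d0) return(0)
    if (has_sp[lost]) costs$los1 else costs$los2
  }
  trn <- function(donor) if (gain && St$outgroup[donor]) costs$gain else costs$tr_nor
  trr <- function(donor) if (gain && St$outgroup[donor]) costs$gain else costs$tr_ret
  dupc <- function(d) if (gain && St$outgroup[d]) 0 else costs$dup
  divc <- function(d) if (gain && d == d0) 0 else costs$div
  dstar <- if (gain) which(St$outgroup & !is.na(S0$rank) & S0$rank == 0L) else integer(0)

  f <- function(e, d) {
    ech <- G$children[[e]]
    dch <- St$children[[d]]
    mates <- slice_mates(S0, d, include_outgroup = !gain)
    if (!length(ech) && !length(dch)) {
      dp <- leafmap[[G$species[e]]]
      return(if (d == dp) 0 else trn(d))
    }
    alts <- c()
    if (length(dch) == 1L) alts <- c(alts, f(e, dch[1]))
    if (length(dch) == 2L) {
      alts <- c(alts,
                f(e, dch[1]) + loss_of(dch[2], d),
                f(e, dch[2]) + loss_of(dch[1], d))
    }
    if (length(ech)) {
      alts <- c(alts, f(ech[1], d) + f(ech[2], d) + dupc(d))
      if (length(dch) == 2L) {
        alts <- c(alts,
                  f(ech[1], dch[1]) + f(ech[2], dch[2]) + divc(d),
                  f(ech[2], dch[1]) + f(ech[1], dch[2]) + divc(d))
      }
      if (gain && d == d0) {
        alts <- c(alts,
                  f(ech[1], d0) + f(ech[2], dstar),
                  f(ech[2], d0) + f(ech[1], dstar))
      }
      for (dp in mates) {
        alts <- c(alts,
                  f(ech[1], d) + f(ech[2], dp) + trr(d),
                  f(ech[2], d) + f(ech[1], dp) + trr(d))
      }
    }
    for (dp in mates) {
      dpch <- St$children[[dp]]
      if (length(dpch) == 1L) alts <- c(alts, f(e, dpch[1]) + trn(d))
      if (length(dpch) == 2L) {
        alts <- c(alts,
                  f(e, dpch[1]) + trn(d) + loss_of(dpch[2], dp),
                  f(e, dpch[2]) + trn(d) + loss_of(dpch[1], dp))
      }
      if (length(ech)) {
        alts <- c(alts, f(ech[1], dp) + f(ech[2], dp) + trn(d) + dupc(dp))
        if (length(dpch) == 2L) {
          alts <- c(alts,
                    f(ech[1], dpch[1]) + f(ech[2], dpch[2]) + trn(d) + divc(dp),
                    f(ech[2], dpch[1]) + f(ech[1], dpch[2]) + trn(d) + divc(dp))
        }
        for (ds in setdiff(slice_mates(S0, dp, include_outgroup = !gain), d)) {
          alts <- c(alts,
                    f(ech[1], dp) + f(ech[2], ds) + trn(d) + trr(dp),
                    f(ech[2], dp) + f(ech[1], ds) + trn(d) + trr(dp))
        }
      }
    }
    if (!length(alts)) Inf else min(alts)
  }
  f(G$root, d0)
}

# every candidate binarization of a polytomous tree, deduplicated by topology
oracle_candidate_binarizations <- function(G) {
  seen <- new.env(parent = emptyenv())
  out <- list()
  rec <- function(t) {
    poly <- which(lengths(t$children) > 2L)
    if (!length(poly)) {
      k <- canon_newick(t)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        out[[length(out) + 1L]] <<- t
      }
      return(invisible(NULL))
    }
    g <- poly[1]
    ch <- t$children[[g]]
    n <- length(ch)
    for (mask in 0:(2^(n - 1) - 1)) {           # ch[1] always in A
      inA <- c(TRUE, as.logical(intToBits(mask)[seq_len(n - 1)]))
      A <- ch[inA]; B <- ch[!inA]
      if (!length(B)) next
      rec(binarization_step(t, g, A, B))
    }
  }
  rec(G)
  out
}

# total canonical reconciliation cost of a set of gene trees into S
total_alpha_cost <- function(Gjs, S, costs = event_costs()) {
  sum(vapply(Gjs, function(G) infer_events(G, S, costs = costs)$total_cost,
             numeric(1)))
}

# edges of G2 (a binarization) entering tube d of S, counted directly
count_entering <- function(G2, S, d) {
  sum(vapply(setdiff(seq_len(G2$nv), G2$superroot),
             function(e) enters_tube(G2, S, e, d), logical(1)))
}

random_costs <- function(seed) {
  set.seed(seed)
  u <- stats::runif(7, 0.1, 3)
  event_costs(div = min(u[1], u[2] - 1e-3), dup = u[2], los1 = u[3],
              los2 = u[4], tr_ret = u[5], tr_nor = u[6], gain = u[7])
}
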