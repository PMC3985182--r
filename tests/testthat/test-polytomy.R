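test_that("enters_tube implements the entering relation", {
  G <- gt("((a,b),c);")
  S <- st("((a,c),b);")
  w <- lca_of(S, c("a", "c"))
  leaf_a <- which(G$species == "a" & lengths(G$children) == 0)
  expect_true(enters_tube(G, S, leaf_a, w))
  # termini imaged in the same tube: the edge enters no tube at all
  G2 <- gt("(x@a,y@a);"); S2 <- st("(a,b);")
  cherry <- G2$root                            # alpha maps it into leaf tube a
  leaf_edge <- G2$children[[cherry]][1]
  expect_false(any(vapply(setdiff(seq_len(S2$nv), S2$superroot),
                          function(d) enters_tube(G2, S2, leaf_edge, d),
                          logical(1))))
  # the root edge enters exactly the tubes above its lower image: with the
  # superroot imaged above everything, a root mapped into the root tube makes
  # the root edge enter d0 and nothing else (this is what lets the root edge
  # parent a bundle for the root tube, as the bundle lemmas require)
  G3 <- gt("(a,b);"); S3 <- st("(a,b);")
  entered <- Filter(function(d) enters_tube(G3, S3, G3$root, d),
                    setdiff(seq_len(S3$nv), S3$superroot))
  expect_equal(entered, S3$root)
})

test_that("bundles partition entering edges by upper terminus", {
  G <- gt("((a,b),c);")
  S <- st("((a,c),b);")
  w <- lca_of(S, c("a", "c"))
  bs <- bundles_for(G, S, w)
  expect_length(bs, 2L)                        # two singleton bundles
  expect_true(all(lengths(lapply(bs, `[[`, "edges")) == 1L))
  expect_equal(length(unique(vapply(bs, `[[`, numeric(1), "parent_vertex"))), 2L)

  Gp <- gt("(a,b,c);")
  Sp <- st("((a,b),c);")
  dab <- lca_of(Sp, c("a", "b"))
  bsp <- bundles_for(Gp, Sp, dab)
  expect_length(bsp, 1L)                       # one bundle of two edges
  expect_length(bsp[[1]]$edges, 2L)
  expect_equal(bsp[[1]]$parent_vertex, Gp$root)

  # no species below the tube: nothing enters
  G3 <- gt("(a,b);")
  S3 <- st("((a,b),c);")
  leaf_c <- which(S3$species == "c")
  expect_length(bundles_for(G3, S3, leaf_c), 0L)
})

test_that("binarization steps resolve polytomies as specified", {
  G <- gt("(a,b,c);")
  g <- G$root
  ids <- function(sp) which(G$species %in% sp & lengths(G$children) == 0)
  expect_identical(canon_newick(binarization_step(G, g, ids(c("a", "b")), ids("c"))),
                   canon_newick(gt("((a,b),c);")))
  G4 <- gt("(a,b,c,d);")
  out <- binarization_step(G4, G4$root,
                           which(G4$species == "a"),
                           which(G4$species %in% c("b", "c", "d")))
  expect_identical(canon_newick(out), canon_newick(gt("(a,(b,c,d));")))
  expect_equal(sum(lengths(out$children) == 3L), 1L)  # singleton part: no new vertex
  expect_error(binarization_step(gt("(a,b);"), 4L, 1L, 2L), "not polytomous")
  expect_error(binarization_step(G, g, ids("a"), ids("b")), "partition")
})

test_that("paralogous binarization minimizes entering edges per tube", {
  # fixed examples
  expect_identical(canon_newick(paralogous_binarization(gt("((a,b),c);"),
                                                        st("((a,b),c);"))),
                   canon_newick(gt("((a,b),c);")))      # binary: unchanged
  expect_identical(canon_newick(paralogous_binarization(gt("(a,b,c);"),
                                                        st("((a,b),c);"))),
                   canon_newick(gt("((a,b),c);")))
  expect_identical(canon_newick(paralogous_binarization(gt("(x@a,y@a,b);"),
                                                        st("(a,b);"))),
                   canon_newick(gt("((x@a,y@a),b);")))

  # minimality against the full candidate enumeration, several instances
  cases <- list(
    list(G = gt("(a,b,c,d);"), S = st("((a,b),(c,d));")),
    list(G = gt("(x@a,y@a,b,c);"), S = st("((a,b),c);")),
    list(G = gt("((a,b,c),(d,e));"), S = st("(((a,b),c),(d,e));")),
    list(G = gt("(x@a,y@a,z@a,b);"), S = st("(a,b);")),
    list(G = gt("(a,(b,c,d,e));"), S = st("((a,b),(c,(d,e)));"))
  )
  for (cs in cases) {
    gpp <- paralogous_binarization(cs$G, cs$S)
    expect_true(rt_is_binary(gpp))
    cands <- oracle_candidate_binarizations(cs$G)
    tubes <- setdiff(seq_len(cs$S$nv), cs$S$superroot)
    for (d in tubes) {
      p_gd <- length(bundles_for(cs$G, cs$S, d))
      counts <- vapply(cands, count_entering, numeric(1), S = cs$S, d = d)
      expect_equal(count_entering(gpp, cs$S, d), min(counts),
                   info = sprintf("%s into %s, tube %d", write_newick(cs$G),
                                  write_newick(cs$S), d))
      expect_equal(min(counts), p_gd)          # the minimum is the bundle count
    }
  }
})

test_that("all paralogous binarizations of one instance cost the same", {
  cases <- list(
    list(G = gt("(x@a,y@a,z@a,b);"), S = st("(a,b);")),
    list(G = gt("(a,b,c,d);"), S = st("((a,b),(c,d));")),
    list(G = gt("(x@a,y@a,b,c);"), S = st("((a,b),c);"))
  )
  for (cs in cases) {
    cands <- oracle_candidate_binarizations(cs$G)
    tubes <- setdiff(seq_len(cs$S$nv), cs$S$superroot)
    is_parb <- vapply(cands, function(g2)
      all(vapply(tubes, function(d)
        count_entering(g2, cs$S, d) == length(bundles_for(cs$G, cs$S, d)),
        logical(1))), logical(1))
    expect_true(any(is_parb))
    costs <- vapply(cands[is_parb], function(g2)
      infer_events(g2, cs$S)$total_cost, numeric(1))
    expect_equal(length(unique(costs)), 1L)
    # and the constructed one is among them at that cost
    gpp <- paralogous_binarization(cs$G, cs$S)
    expect_equal(infer_events(gpp, cs$S)$total_cost, costs[1])
  }
})

test_that("bundle parents biject with entering edges in G##", {
  cases <- list(
    list(G = gt("(x@a,y@a,b,c);"), S = st("((a,b),c);")),
    list(G = gt("(a,(b,c,d,e));"), S = st("((a,b),(c,(d,e)));"))
  )
  for (cs in cases) {
    gpp <- paralogous_binarization(cs$G, cs$S)
    for (d in setdiff(seq_len(cs$S$nv), cs$S$superroot)) {
      expect_equal(count_entering(gpp, cs$S, d),
                   length(bundles_for(cs$G, cs$S, d)))
    }
  }
})

test_that("Par' equals leaves-minus-bundles and reduces to Par on binary trees", {
  S <- st("(a,b);")
  expect_equal(par_prime(gt("(x@a,y@a,z@a);"), S, "a"), 2L)
  expect_equal(par_prime(gt("((a,b),c);"), st("((a,b),c);"), "a"), 0L)
  expect_error(par_prime(gt("(a,b);"), S, "zz"), "unknown species")
  # binary gene trees: Par' == Par for every species, random instances
  set.seed(8)
  for (rep in 1:15) {
    Sr <- random_species_tree(letters[1:3], seed = rep)
    G <- random_gene_tree(letters[1:3], sample(3:6, 1), seed = 40 + rep)
    for (s in letters[1:3])
      expect_equal(par_prime(G, Sr, s), par_count(G, s),
                   info = sprintf("rep %d s=%s", rep, s))
  }
  # explicit-binarization cross-check for the polytomous case
  Gp <- gt("(x@a,y@a,z@a);")
  gpp <- paralogous_binarization(Gp, S)
  inv <- infer_events(gpp, S)
  leaf_a <- which(S$species == "a")
  expect_equal(sum(inv$duplications$tube == leaf_a), par_prime(Gp, S, "a"))
})

test_that("the bundle census matches the explicit-binarization event counts", {
  # join counts on a polytomy, verified against the binarized instance
  Gp <- list(gt("(a,b,c);"))
  p <- poly_q_counts(Gp, c("a", "b"), "c")
  expect_equal(unname(p[c("n", "n1", "n2", "k")]), c(1, 1, 1, 1))
  expect_equal(unname(p[c("n1p", "n2p", "kp")]), c(1, 1, 1))
  expect_equal(unname(p[c("n1pp", "n2pp", "kpp")]), c(0, 0, 0))
  # join-level events derived from the census: k = 1 divergence at the root,
  # n1+n2-n-k = 0 duplications, no losses; the full alpha reconciliation of
  # the binarization ((a,b),c) adds only the inner {a,b} divergence
  expect_equal(unname(p["n1"] + p["n2"] - p["n"] - p["k"]), 0)
  inv <- infer_events(paralogous_binarization(Gp[[1]], st("((a,b),c);")),
                      st("((a,b),c);"))
  expect_equal(nrow(inv$divergences), 2L)
  expect_equal(nrow(inv$duplications), 0L)
  expect_equal(nrow(inv$losses), 0L)
  # no species of the halves: all zeros
  p0 <- poly_q_counts(list(gt("(x@d,y@d);")), c("a", "b"), "c")
  expect_true(all(p0 == 0))
})

test_that("polytomous phase 1 coincides with the binary recursion on binary input", {
  set.seed(17)
  for (rep in 1:8) {
    Gjs <- lapply(1:2, function(i)
      random_gene_tree(letters[1:4], sample(3:5, 1), seed = rep * 7 + i))
    t1 <- phase1(Gjs)
    t2 <- phase1_polytomous(Gjs)
    expect_equal(names(t1$basic)[t1$basic], names(t2$basic)[t2$basic])
    for (k in names(t1$basic)[t1$basic]) {
      e1 <- get(k, envir = t1$entries); e2 <- get(k, envir = t2$entries)
      expect_equal(e1$cost, e2$cost, info = k)
      expect_identical(canon_newick(e1$tree), canon_newick(e2$tree))
    }
  }
})

test_that("polytomous phase 1 resolves a root polytomy through the clade family", {
  P <- clade_family(letters[1:3],
                    list("a", "b", "c", c("a", "b"), c("a", "b", "c")))
  tab <- phase1_polytomous(list(gt("(a,b,c);")), P)
  expect_false(is.na(tab$supertree_key))
  e <- get(tab$supertree_key, envir = tab$entries)
  expect_identical(canon_newick(e$tree), canon_newick(st("((a,b),c);")))
  expect_equal(e$cost, 0)                      # one free divergence
  # paralog polytomy singleton: two duplications
  tabs <- phase1_polytomous(list(gt("(x@a,y@a,z@a);")),
                            clade_family("a", list("a")))
  expect_equal(get("a", envir = tabs$entries)$cost, 2 * event_costs()$dup)
})

test_that("Eq-12 costs equal the alpha cost of the explicit binarization", {
  # polytomous instances: phase-1 optimum == direct cost of binarized trees
  set.seed(23)
  for (rep in 1:5) {
    Gjs <- list(gt("(a,b,c,d);"), random_gene_tree(letters[1:4], 4,
                                                   seed = 60 + rep))
    members <- unlist(lapply(1:4, function(k)
      utils::combn(letters[1:4], k, simplify = FALSE)), recursive = FALSE)
    P <- clade_family(letters[1:4], members)
    tab <- phase1_polytomous(Gjs, P)
    c_v0 <- get(tab$supertree_key, envir = tab$entries)$cost
    best <- min(vapply(enumerate_rooted_trees(letters[1:4]), function(S)
      sum(vapply(Gjs, function(g)
        infer_events(paralogous_binarization(g, S), S)$total_cost,
        numeric(1))), numeric(1)))
    expect_equal(c_v0, best, info = paste("rep", rep))
  }
})
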