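toy_records <- function() {
  data.frame(
    query = c("g1", "g2", "g3", "g1", "g1", "g2"),
    target = c("g1", "g2", "g3", "g2", "g3", "g3"),
    bitscore = c(100, 80, 90, 50, 20, 3),
    qalnfrac = c(1, 1, 1, 0.8, 0.9, 0.3),
    talnfrac = c(1, 1, 1, 0.7, 0.8, 0.9),
    stringsAsFactors = FALSE)
}

test_that("Hscore follows the scaled bit-score-ratio definition", {
  edges <- build_graph(toy_records())
  e12 <- edges[edges$gene1 == "g1" & edges$gene2 == "g2", ]
  expect_equal(e12$hscore, 100 * 50 / max(100, 80))  # = 50
  # aligned fraction 0.3 on one side kills the g2-g3 edge
  expect_equal(nrow(edges[edges$gene1 == "g2" & edges$gene2 == "g3", ]), 0)
  # a self comparison would score 100 by construction
  expect_equal(100 * 100 / max(100, 100), 100)
})

test_that("Hscore is symmetric in the gene order of records", {
  rec <- toy_records()
  swapped <- rec
  swapped[c("query", "target")] <- rec[c("target", "query")]
  swapped[c("qalnfrac", "talnfrac")] <- rec[c("talnfrac", "qalnfrac")]
  e1 <- build_graph(rec)
  e2 <- build_graph(swapped)
  expect_equal(e1[order(e1$gene1, e1$gene2), ],
               e2[order(e2$gene1, e2$gene2), ], ignore_attr = TRUE)
})

test_that("genes without self hits fall back to their best score", {
  rec <- toy_records()[-1, ]     # drop g1's self hit
  edges <- build_graph(rec)
  expect_equal(attr(edges, "n_self_fallback"), 1)
  e12 <- edges[edges$gene1 == "g1" & edges$gene2 == "g2", ]
  expect_equal(e12$hscore, 100 * 50 / 80)
})

test_that("a one-gene family simulates to a single self-hit record", {
  sim <- simulate_similarity_graph(1, 1, seed = 1)
  expect_equal(nrow(sim$records), 1)
  expect_equal(sim$records$query, sim$records$target)
  expect_false(sim$overlap_warning)
})

test_that("an isolated gene comes out as a singleton family", {
  rec <- data.frame(query = "lonely", target = "lonely", bitscore = 42,
                    qalnfrac = 1, talnfrac = 1)
  fam <- cluster_families(build_graph(rec))
  expect_equal(nrow(fam), 1)
  expect_equal(fam$size, 1)
  expect_equal(fam$genes, "lonely")
})

test_that("planted families are recovered exactly when separable", {
  sim <- simulate_similarity_graph(3, c(5, 4, 3),
                                   within_hscore = c(40, 90),
                                   between_hscore = c(0, 3), seed = 2)
  fam <- cluster_families(build_graph(sim$records))
  membership <- attr(fam, "membership")
  got <- split(names(membership), membership)
  want <- split(names(sim$truth), sim$truth)
  norm <- function(p) unname(lapply(p, sort)[order(vapply(p, min, ""))])
  expect_equal(norm(got), norm(want))
})

test_that("cross-family edges below the weight threshold never merge families", {
  sim <- simulate_similarity_graph(2, c(4, 4),
                                   within_hscore = c(40, 80),
                                   between_hscore = c(4.5, 4.9), seed = 3)
  fam <- cluster_families(build_graph(sim$records), min_hscore = 5)
  expect_equal(nrow(fam), 2)
})

test_that("overlapping score ranges trigger the warning flag", {
  expect_warning(
    sim <- simulate_similarity_graph(2, 3, within_hscore = c(10, 50),
                                     between_hscore = c(5, 20), seed = 1),
    "overlap")
  expect_true(sim$overlap_warning)
})

test_that("a family holding an outgroup gene accepts no further members", {
  # chain a-b-c where b is an outgroup gene with the strongest edges
  rec <- data.frame(
    query = c("a", "b", "c", "a", "b"),
    target = c("a", "b", "c", "b", "c"),
    bitscore = c(100, 100, 100, 90, 80),
    qalnfrac = 1, talnfrac = 1)
  fam <- cluster_families(build_graph(rec), outgroup = "b")
  # a+b merge first (Hscore 90); the resulting family contains the
  # outgroup and must refuse c even though b-c scores 80
  expect_equal(nrow(fam), 2)
  merged <- fam[fam$size == 2, ]
  expect_equal(merged$genes, "a,b")
  expect_true(merged$contains_outgroup)
})

test_that("raising the Hscore threshold only refines families", {
  sim <- simulate_similarity_graph(3, c(6, 5, 4),
                                   within_hscore = c(10, 90),
                                   between_hscore = c(0, 4), seed = 5)
  edges <- build_graph(sim$records)
  sizes <- function(th) {
    fam <- cluster_families(edges, min_hscore = th)
    m <- attr(fam, "membership")
    vapply(names(m), function(g) sum(m == m[g]), numeric(1))
  }
  s5 <- sizes(5); s30 <- sizes(30); s60 <- sizes(60)
  expect_true(all(s30 <= s5))
  expect_true(all(s60 <= s30))
})

test_that("clustering is invariant to record order", {
  sim <- simulate_similarity_graph(3, c(4, 4, 4), seed = 7)
  rec <- sim$records
  set.seed(1)
  shuffled <- rec[sample(nrow(rec)), ]
  f1 <- cluster_families(build_graph(rec))
  f2 <- cluster_families(build_graph(shuffled))
  expect_equal(f1, f2, ignore_attr = TRUE)
})

test_that("sharing summaries count exclusive and inclusive matches", {
  fams <- list(c("a1", "a2"), c("b1", "b2"), c("c1"), c("d1", "d2"),
               c("e1", "e2", "e3"))
  sp <- c(a1 = "cheetah", a2 = "cat", b1 = "cheetah", b2 = "cheetah",
          c1 = "cat", d1 = "cheetah", d2 = "cat",
          e1 = "cheetah", e2 = "cat", e3 = "tiger")
  out <- sharing_summary(fams, sp,
                         combinations = list(c("cheetah", "cat"),
                                             "cheetah",
                                             c("cheetah", "cat", "tiger")))
  expect_equal(out$exclusive, c(2, 1, 1))
  expect_equal(out$inclusive, c(3, 4, 1))
  # exclusive counts over all observed combinations partition the families
  all_out <- sharing_summary(fams, sp)
  expect_equal(sum(all_out$exclusive), length(fams))
  expect_error(sharing_summary(list(c("zz")), sp), "zz")
})
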